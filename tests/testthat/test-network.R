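p0 <- quick_params()

test_that("partial reset follows the stated rule and its monotonicity", {
  # full reset discards the whole overshoot
  expect_equal(apply_reset(p0$v_peak + 10, 0, p0), p0$v_reset)
  # direct substitution: v_reset + theta * (v - v_peak)
  expect_equal(apply_reset(35, 1, p0), -60)
  # zero overshoot resets to v_reset for any theta
  expect_equal(apply_reset(p0$v_peak, 0.7, p0), p0$v_reset)
  # nondecreasing in theta and in overshoot
  th <- seq(0, 1, by = 0.1)
  expect_true(all(diff(apply_reset(40, th, p0)) >= 0))
  ov <- seq(0, 20, by = 2)
  expect_true(all(diff(apply_reset(p0$v_peak + ov, 0.5, p0)) >= 0))
  expect_error(apply_reset(p0$v_peak - 1, 0, p0), "v_above")
})

test_that("network initialization is seeded and respects degenerate widths", {
  het <- het_spec(eta_bar = 1000, delta_eta = 0, g_bar = 15, delta_g = 0,
                  theta_bar = 0.3, delta_theta = 0)
  st <- init_network(p0, het, 10, seed = 4)
  expect_identical(st$eta, rep(1000, 10))
  expect_identical(st$g, rep(15, 10))
  expect_identical(st$theta, rep(0.3, 10))
  expect_true(all(st$v >= p0$v_r & st$v <= p0$v_t))
  st2 <- init_network(p0, het, 10, seed = 4)
  expect_identical(st, st2)
  expect_error(init_network(p0, het, 0), "n must be")
})

test_that("gating variable decays exponentially and jumps by s_jump/N", {
  het <- het_spec(eta_bar = 0, delta_eta = 0, g_bar = 0)  # silent, uncoupled
  st <- init_network(p0, het, 10, seed = 1)
  st$s <- 1
  dt <- 0.05
  n_steps <- round(p0$tau_s / dt)
  for (i in seq_len(n_steps)) st <- step_network(st, p0, dt = dt)$state
  expect_rel(st$s, exp(-1), 1e-9)  # exact decay, no Euler error
  # a single spiking neuron adds s_jump / N
  p8 <- quick_params(s_jump = 0.8)
  st <- init_network(p8, het, 10, seed = 1)
  st$v[3] <- p8$v_peak + 50  # force one neuron over threshold next step
  st$eta[3] <- 1e5
  out <- step_network(st, p8, dt = dt)
  expect_equal(out$spiked, 3L)
  expect_equal(out$state$s, 0.8 / 10)
})

test_that("identical uncoupled neurons stay in lockstep", {
  het <- het_spec(eta_bar = 1500, delta_eta = 0, g_bar = 0)
  st <- init_network(p0, het, 5, seed = 2)
  st$v <- rep(-50, 5)
  in_lockstep <- TRUE
  spikes_joint <- TRUE
  for (i in 1:4000) {
    out <- step_network(st, p0, dt = 0.05)
    st <- out$state
    in_lockstep <- in_lockstep && length(unique(st$v)) == 1
    if (length(out$spiked))
      spikes_joint <- spikes_joint && identical(out$spiked, 1:5)
  }
  expect_true(in_lockstep)
  expect_true(spikes_joint)
  expect_gt(st$s, 0)  # they did spike
})

test_that("compiled simulator agrees with the R reference step exactly", {
  het <- het_spec(eta_bar = 1100, delta_eta = 5, g_bar = 15,
                  theta_bar = 0.4, delta_theta = 0.1)
  st <- init_network(p0, het, 20, seed = 9)
  dt <- 0.05
  sim <- simulate_network(p0, duration = 50, dt = dt, sample_every = 1,
                          state = st, drive = 200, record_v = TRUE,
                          record_w = TRUE)
  st_r <- st
  for (i in seq_len(round(50 / dt))) st_r <- step_network(st_r, p0, 200, dt)$state
  expect_equal(sim$state$v, st_r$v, tolerance = 1e-12)
  expect_equal(sim$state$w, st_r$w, tolerance = 1e-12)
  expect_equal(sim$state$s, st_r$s, tolerance = 1e-12)
})

test_that("gating bookkeeping is exact against the raster", {
  het <- het_spec(eta_bar = 1200, delta_eta = 5, g_bar = 15)
  sim <- simulate_network(p0, het, 100, duration = 500, dt = 0.05, seed = 3)
  # reconstruct s at the end of the run from the raster alone
  tend <- 500
  contrib <- sum(exp(-(tend - (sim$raster$time_ms + sim$dt)) / p0$tau_s)) *
    p0$s_jump / 100
  expect_rel(sim$state$s, contrib, 1e-9)
  # filtered traces match the closed-form convolution oracle
  j <- which.max(tabulate(sim$raster$neuron, 100))
  spikes_j <- sim$raster$time_ms[sim$raster$neuron == j]
  oracle <- filter_oracle(spikes_j, sim$trace_times, p0$tau_s, sim$dt)
  expect_lt(max(abs(sim$filtered[, j] - oracle)), 1e-8)
})

test_that("a subthreshold neuron stays silent at the stable fixed point", {
  # rheobase is k ((v_t - v_r)/2)^2 = 1000 pA for the default preset
  st <- single_neuron_state(p0, eta = 600)
  sim <- simulate_network(p0, duration = 2000, dt = 0.05, state = st,
                          record_v = TRUE)
  expect_equal(nrow(sim$raster), 0)
  # root-finding oracle: stable root of k(v - v_r)(v - v_t) + eta = 0
  roots <- sort(Re(polyroot(c(p0$k * p0$v_r * p0$v_t + 600,
                              -p0$k * (p0$v_r + p0$v_t), p0$k))))
  expect_rel(sim$state$v, roots[1], 1e-3)
})

test_that("spike-time convergence is first order in dt", {
  isi <- function(dt) {
    st <- single_neuron_state(p0, eta = 1500)
    sim <- simulate_network(p0, duration = 400, dt = dt, state = st)
    diff(sim$raster$time_ms)[5]  # a settled interspike interval
  }
  ref <- isi(0.0005)
  expect_rel(isi(0.01), ref, 0.01)
  err <- c(abs(isi(0.04) - ref), abs(isi(0.02) - ref), abs(isi(0.01) - ref))
  # halving dt roughly halves the spike-time error (order-1 Euler)
  expect_gt(err[1] / err[2], 1.3)
  expect_gt(err[2] / err[3], 1.3)
})

test_that("simulation guards and population rates behave", {
  het <- het_spec(eta_bar = 1100, delta_eta = 1)
  expect_error(simulate_network(p0, het, 10, duration = 0), "duration")
  expect_error(simulate_network(p0, het, 10, duration = 10, dt = 0.3,
                                sample_every = 1), "divide")
  sim <- simulate_network(p0, het, 4, duration = 100, dt = 0.05, seed = 1,
                          drive = make_pulse(500, 10, 20))
  expect_error(population_rate(sim, 200), "longer")
  expect_error(population_rate(sim, 0), "window")
  # empty raster gives an all-zero series
  quiet <- simulate_network(p0, homogeneous_spec(eta_bar = 0), 4,
                            duration = 50, dt = 0.05, seed = 1)
  expect_true(all(population_rate(quiet, 10)$rate == 0))
  # rate additivity: one window is the duration-weighted mean of halves
  r10 <- population_rate(sim, 50)
  r5 <- population_rate(sim, 25)
  expect_equal(r10$rate[1], mean(r5$rate[1:2]))
})

test_that("rate counting matches the direct definition", {
  # N = 4 neurons, one spike each inside a 10 ms window -> 0.1 kHz
  sim <- list(raster = data.frame(time_ms = c(1, 3, 5, 7),
                                  neuron = 1:4),
              n = 4, duration = 10, t0 = 0)
  class(sim) <- "snn_sim"
  expect_equal(population_rate(sim, 10)$rate, 0.1)
})

test_that("raster and trace exports round trip through CSV", {
  het <- het_spec(eta_bar = 1150, delta_eta = 2)
  sim <- simulate_network(p0, het, 20, duration = 200, dt = 0.05, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_raster(sim, f)
  back <- read_raster(f)
  expect_equal(back$time_ms, sim$raster$time_ms)
  expect_equal(back$neuron, sim$raster$neuron)
  f2 <- tempfile(fileext = ".csv")
  write_traces(sim, f2)
  tr <- utils::read.csv(f2)
  expect_equal(tr$time_ms, sim$trace_times)
  expect_equal(tr$r3, sim$filtered[, 3], tolerance = 1e-9)
})

test_that("drive specifications compose additively", {
  t <- c(0, 5, 15, 30)
  p1 <- make_pulse(100, 0, 10)
  p2 <- make_pulse(50, 5, 20)
  expect_equal(hetsnn:::eval_drive(list(p1, p2), t), c(100, 150, 50, 0))
  expect_equal(hetsnn:::eval_drive(function(tt) 2 * tt, t), 2 * t)
  expect_equal(hetsnn:::eval_drive(NULL, t), rep(0, 4))
})
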