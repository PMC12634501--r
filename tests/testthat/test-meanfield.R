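p0 <- quick_params()

test_that("mean-field rhs satisfies its structural identities", {
  het <- het_spec(eta_bar = 1100, delta_eta = 0, g_bar = 15)
  # r = 0 is invariant without drive heterogeneity
  d <- meanfield_rhs(c(0, -50, 10, 0.1), p0, het)
  expect_equal(d[1], 0)
  # steady-state gating: s* = tau_s * s_jump * r*
  r <- 0.01
  s_star <- p0$tau_s * p0$s_jump * r
  d <- meanfield_rhs(c(r, -45, 5, s_star), p0, het)
  expect_equal(d[4], 0)
  # steady-state adaptation with no spikes: w* = beta (v - v_r)
  pb <- quick_params(beta = 2)
  d <- meanfield_rhs(c(0, -50, 2 * (-50 - pb$v_r), 0), pb,
                     het_spec(eta_bar = 0, delta_eta = 0, g_bar = 15))
  expect_equal(d[3], 0)
  expect_error(meanfield_rhs(c(-0.01, -50, 0, 0), p0, het), "negative")
  expect_error(meanfield_rhs(c(0, -50, 0, 0), p0,
                             het_spec(delta_g = 1)), "delta_g")
})

test_that("trajectories respect invariance and fixed-point stability", {
  # without drive heterogeneity the silent state is invariant (the mean
  # voltage escapes in finite time there, so integrate only briefly)
  het0 <- het_spec(eta_bar = 1100, delta_eta = 0, g_bar = 15)
  traj <- integrate_meanfield(c(0, -55, 0, 0), p0, het0, duration = 30,
                              dt = 0.1)
  expect_true(all(traj$r == 0))
  # start at a computed stable fixed point and stay there
  het1 <- het_spec(eta_bar = 900, delta_eta = 1, g_bar = 15)
  fp <- find_fixed_points(p0, het1)
  stable <- Filter(function(f) f$stable, fp)
  expect_gte(length(stable), 1)
  x0 <- stable[[1]]$state
  traj <- integrate_meanfield(x0, p0, het1, duration = 1000)
  expect_lt(max(abs(traj$r - x0[1])), 1e-6)
})

test_that("fixed points satisfy the residual contract and regime examples", {
  het <- het_spec(delta_eta = 1, g_bar = 15)
  # far below the oscillatory window: one stable, near-silent fixed point
  fps <- find_fixed_points(p0, het, eta_bar = 600)
  expect_true(any(vapply(fps, function(f) f$stable, logical(1))))
  st <- Filter(function(f) f$stable, fps)[[1]]
  expect_lt(st$state[1], 1e-3)
  # far above: a stable fixed point with substantial rate
  fps2 <- find_fixed_points(p0, het, eta_bar = 1300)
  st2 <- Filter(function(f) f$stable, fps2)
  expect_gte(length(st2), 1)
  expect_gt(st2[[1]]$state[1], 1e-3)
  # every returned root has a tiny rhs residual
  for (f in c(fps, fps2)) {
    h <- het; h$eta_bar <- if (f$state[1] > 1e-3) 1300 else 600
    expect_lt(max(abs(meanfield_rhs(f$state, p0, h))), 1e-8)
  }
})

test_that("oscillatory-window integration settles on a stationary cycle", {
  het <- het_spec(eta_bar = 1100, delta_eta = 1, g_bar = 15)
  traj <- integrate_meanfield(c(0.003, -50, 0, 0.05), p0, het,
                              duration = 5000, dt = 1)
  r <- traj$r[traj$time > 2500]
  n <- length(r)
  a <- r[seq_len(n %/% 2)]
  b <- r[(n %/% 2 + 1):n]
  # peak-to-peak amplitude stationary across the two halves within 5%
  expect_rel(max(b) - min(b), max(a) - min(a), 0.05)
})

test_that("the default preset has exactly two Hopf points bracketing the
           oscillatory window, robust to scan direction", {
  het <- het_spec(delta_eta = 1, g_bar = 15)
  grid <- seq(800, 1400, by = 25)
  bif <- scan_bifurcation(p0, het, grid, n_cycle_probe = 2)
  expect_length(bif$hopf, 2)
  expect_true(all(diff(bif$hopf) > 0))
  # the leading eigenvalue changes sign across each detected Hopf point
  b <- bif$branch
  for (h in bif$hopf) {
    below <- b$lead_re[max(which(b$eta_bar < h))]
    above <- b$lead_re[min(which(b$eta_bar > h))]
    expect_lt(below * above, 0)
  }
  # cycle extrema were recorded inside the window
  expect_true(any(!is.na(b$r_cycle_max)))
  expect_true(all(b$r_cycle_max >= b$r_cycle_min, na.rm = TRUE))
  # scanning in reverse yields the same special points
  bif_rev <- scan_bifurcation(p0, het, grid, n_cycle_probe = 0)
  expect_equal(bif_rev$hopf, bif$hopf, tolerance = 1e-3)
  expect_error(scan_bifurcation(p0, het, rev(grid)), "increasing")
})

test_that("regimes are classified in the order quiescent, oscillatory,
           persistent", {
  het <- het_spec(delta_eta = 1, g_bar = 15)
  expect_equal(classify_regime(p0, het, 900)$label, "quiescent")
  osc <- classify_regime(p0, het, 1100)
  expect_equal(osc$label, "oscillatory")
  expect_gt(diff(osc$cycle_r_range), 0.001)
  expect_equal(classify_regime(p0, het, 1300)$label, "persistent")
})

test_that("bifurcation export writes branch CSV plus special-point JSON", {
  het <- het_spec(delta_eta = 1, g_bar = 15)
  bif <- scan_bifurcation(p0, het, seq(1000, 1060, by = 20),
                          n_cycle_probe = 0)
  f <- tempfile(fileext = ".csv")
  write_bifurcation(bif, f)
  d <- utils::read.csv(f)
  expect_named(d, c("eta_bar", "r_fixed", "stability", "r_cycle_min",
                    "r_cycle_max"))
  j <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                           simplifyVector = TRUE)
  expect_equal(unlist(j$hopf_eta_bar), bif$hopf, tolerance = 1e-12)
})
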