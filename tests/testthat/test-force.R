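test_that("static weights and encoders follow the sampling scheme", {
  cfg <- force_config(n = 1000, seed = 8)
  net <- init_force(cfg)
  # same seed twice: identical draws
  net2 <- init_force(cfg)
  expect_identical(net$omega0, net2$omega0)
  expect_identical(net$enc, net2$enc)
  # density close to p_static
  expect_rel(mean(net$omega0 != 0), cfg$p_static, 0.05)
  # moment oracle: E row sum of |omega0| = p n sigma sqrt(2/pi) with
  # sigma = 1/sqrt(p n), i.e. sqrt(p n) sqrt(2/pi)
  expected <- sqrt(cfg$p_static * cfg$n) * sqrt(2 / pi)
  expect_rel(mean(rowSums(abs(net$omega0))), expected, 0.1)
  expect_true(all(net$enc >= -1 & net$enc <= 1))
  # homogeneous spec gives unit recurrent gain everywhere
  expect_identical(net$g_scale, rep(1, 1000))
})

test_that("zero gains reduce the loop to uncoupled neurons and zero
           targets leave the decoder untouched", {
  het <- het_spec(eta_bar = 1200, delta_eta = 5, g_bar = 15)
  cfg <- force_config(G = 0, Q = 0, n = 50, train_duration = 300,
                      test_duration = 100, het = het, seed = 2)
  # target identically zero: phi stays at zero and the output stays zero
  fit <- force_train(cfg, target_series = rep(0, round(400 / cfg$dt)))
  expect_identical(fit$phi, rep(0, 50))
  expect_equal(fit$mse_test, 0)
  # with G = Q = 0 the spike pattern matches independent neurons
  cfg1 <- cfg; cfg1$n <- 1L
  net <- init_force(cfg)
  st <- init_network(quick_params(),
                     het_spec(eta_bar = 0, delta_eta = 0, g_bar = 0),
                     n = 50, seed = 1)
  st$v <- net$v0; st$eta <- net$eta; st$theta <- net$theta
  sim <- simulate_network(quick_params(), duration = 400, dt = cfg$dt,
                          state = st)
  expect_equal(fit$total_spikes, nrow(sim$raster)) # same spike pattern
})

test_that("the inverse-correlation matrix stays symmetric positive
           definite through training", {
  het <- het_spec(eta_bar = 1100, delta_eta = 20, g_bar = 15)
  cfg <- force_config(G = 500, Q = 500, n = 80, train_duration = 500,
                      test_duration = 100, rls_interval = 10,
                      het = het, seed = 3)
  fit <- force_train(cfg, return_P = TRUE)
  expect_lt(max(abs(fit$P - t(fit$P))), 1e-8)
  ev <- eigen((fit$P + t(fit$P)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("the closed-loop RLS state equals batch ridge on the feature
           stream it saw", {
  het <- het_spec(eta_bar = 1150, delta_eta = 20, g_bar = 15)
  cfg <- force_config(G = 0, Q = 0, n = 40, train_duration = 400,
                      test_duration = 100, rls_interval = 10,
                      lambda_rls = 0.05, het = het, seed = 4)
  # with G = Q = 0 the features do not depend on phi, so the online
  # updates must land exactly on the batch ridge solution over the
  # update-time samples
  nsteps <- round(500 / cfg$dt)
  y <- make_target("y1", seq_len(nsteps) * cfg$dt)
  fit <- force_train(cfg, target_series = y, record_every = 10,
                     record_rr = TRUE, return_P = TRUE)
  upd <- seq(cfg$rls_interval, round(400 / cfg$dt), by = cfg$rls_interval)
  X <- fit$rr_trace[upd / 10, , drop = FALSE]  # record_every = interval
  batch <- train_readout(X, y[upd], lambda = cfg$lambda_rls)
  expect_lt(max(abs(fit$phi - coef(batch))), 1e-6)
})

test_that("a single-cell grid reduces to one training run", {
  het <- het_spec(eta_bar = 1150, delta_eta = 20, g_bar = 15)
  cfg <- force_config(G = 800, Q = 800, n = 60, train_duration = 400,
                      test_duration = 200, het = het, seed = 5)
  g <- gq_grid(cfg, 800, 800, list(only = het), n_seeds = 1,
               csv_dir = d <- tempfile())
  single <- force_train(cfg)
  expect_equal(g$median_log_mse, single$log_mse_test)
  expect_equal(g$viable, single$log_mse_test < 0)
  m <- utils::read.csv(file.path(d, "gq_only.csv"), row.names = 1)
  expect_equal(m[1, 1], single$log_mse_test, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(d, "gq_manifest.json"))
  expect_equal(manifest$settings[[1]], "only")
})

test_that("configuration guards reject degenerate setups", {
  expect_error(force_config(G = -1), "G, Q")
  expect_error(force_config(p_static = 0), "p_static")
  expect_error(force_config(n = 1), "n must be")
  expect_error(force_config(tau_rise = 30), "tau_rise")
})
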