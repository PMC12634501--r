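p0 <- quick_params()

test_that("benchmark targets evaluate to their closed-form values", {
  expect_equal(make_target("y1", 0), 0)
  expect_equal(make_target("y1", 1000 / 24), 1)          # sin(pi/2)
  expect_equal(make_target("y2", 1000 / 48), sqrt(2) / 2) # sin(pi/4) sin(pi/2)
  expect_error(make_target("nope", 0), "unknown target")
})

test_that("feature collection splits contiguously without overlap", {
  het <- het_spec(eta_bar = 1150, delta_eta = 2)
  sim <- simulate_network(p0, het, 30, duration = 1000, dt = 0.05, seed = 2)
  fs <- collect_features(sim, train_fraction = 0.5)
  expect_equal(nrow(fs$X_train), 500)
  expect_equal(nrow(fs$X_test), 500)
  expect_lt(max(fs$times_train), min(fs$times_test))
  expect_equal(ncol(fs$X_train), 31)  # bias column appended
  expect_true(all(fs$X_train[, 31] == 1))
  expect_error(collect_features(sim, 0.005), "fewer than 10")
})

test_that("ridge readout recovers an exact linear rule and shrinks", {
  set.seed(1)
  X <- matrix(rnorm(200 * 10), 200, 10)
  phi0 <- rnorm(10)
  y <- drop(X %*% phi0)
  dec <- train_readout(X, y, lambda = 0)
  expect_lt(max(abs(coef(dec) - phi0)), 1e-8)
  expect_lt(dec$mse_train, 1e-16)
  # enormous penalty drives the weights to zero and the MSE to var(y)
  dec2 <- train_readout(X, y, lambda = 1e12)
  expect_lt(sqrt(sum(coef(dec2)^2)), 1e-4)
  expect_rel(dec2$mse_train, mean(y^2), 1e-3)
  # rank-deficient unpenalized design falls back to minimum norm, flagged
  Xd <- cbind(X, X[, 1])
  dec3 <- train_readout(Xd, y, lambda = 0)
  expect_true(dec3$rank_deficient)
  expect_lt(dec3$mse_train, 1e-16)
  expect_error(train_readout(X, y[-1]), "rows of X")
})

test_that("one-sample recursive updates equal the batch ridge solution", {
  set.seed(42)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- rnorm(50)
  lam <- 0.37
  batch <- train_readout(X, y, lambda = lam)
  rec <- rls_readout(X, y, lambda = lam)
  expect_lt(max(abs(coef(rec) - coef(batch))), 1e-8)
  # the inverse-correlation matrix stays symmetric positive definite
  expect_lt(max(abs(rec$P - t(rec$P))), 1e-10)
  expect_gt(min(eigen(rec$P, symmetric = TRUE, only.values = TRUE)$values), 0)
  # and equals (X'X + lam I)^{-1}
  expect_lt(max(abs(rec$P - solve(crossprod(X) + diag(lam, 20)))), 1e-8)
})

test_that("the trained readout is a stationary point of the ridge loss", {
  set.seed(5)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- rnorm(100)
  dec <- train_readout(X, y, lambda = 0.5)
  obj <- function(phi) sum((X %*% phi - y)^2) + 0.5 * sum(phi^2)
  base <- obj(coef(dec))
  for (k in 1:10) {
    expect_gte(obj(coef(dec) + rnorm(8, 0, 1e-4)), base)
  }
  # evaluate() definitions
  expect_equal(evaluate_readout(dec, X, drop(X %*% coef(dec))), 0)
  zero <- dec; zero$phi <- rep(0, 8)
  expect_equal(evaluate_readout(zero, X, y), mean(y^2))
})

test_that("the reservoir experiment echoes its configuration", {
  het <- het_spec(eta_bar = 1090, delta_eta = 20)
  fit <- run_rls_experiment(p0, het, n = 300, train_duration = 1200,
                            test_duration = 800, settle = 400, seed = 3)
  expect_s3_class(fit, "rls_fit")
  expect_gte(fit$mse_train, 0)
  expect_gte(fit$mse_test, 0)
  expect_equal(fit$config$eta_bar, 1090)
  expect_equal(fit$config$seed, 3)
  # regime_eta overrides the spec's center
  fit2 <- run_rls_experiment(p0, het, n = 300, regime_eta = 700,
                             train_duration = 1200, test_duration = 800,
                             settle = 400, seed = 3)
  expect_equal(fit2$config$eta_bar, 700)
})

test_that("sweeps aggregate per value and reproduce bitwise under a seed", {
  het <- het_spec(eta_bar = 1090, delta_eta = 0)
  base <- list(params = p0, het = het, n = 200, train_duration = 1000,
               test_duration = 600, settle = 300)
  sw <- heterogeneity_sweep("eta", c(0, 5), base, n_seeds = 2,
                            csv = f <- tempfile(fileext = ".csv"))
  expect_equal(nrow(sw$runs), 4)
  expect_equal(nrow(sw$aggregate), 2)
  sw2 <- heterogeneity_sweep("eta", c(0, 5), base, n_seeds = 2)
  expect_identical(sw$runs, sw2$runs)
  agg <- utils::read.csv(sub("\\.csv$", "_aggregate.csv", f))
  expect_equal(agg$mse_test, sw$aggregate$mse_test, tolerance = 1e-12)
  # theta_bar sweeps move the center, not the width
  swt <- heterogeneity_sweep("theta_bar", c(0, 0.5), base, n_seeds = 1)
  expect_equal(swt$aggregate$value, c(0, 0.5))
})
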