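#' Target functions for the curve-fitting experiments
#'
#' The two benchmark targets: a simple sinusoid \code{y1(t) = sin(12 pi t)}
#' and a product of sines \code{y2(t) = sin(12 pi t) sin(24 pi t)}, with
#' \code{t} in seconds (frequencies 6 Hz and a 6/18 Hz mixture). Simulation
#' times are milliseconds, so the conversion is done here.
#'
#' @param name \code{"y1"}, \code{"y2"}, or \code{"harmonics3"} (a
#'   three-harmonic sum used as an extra training target).
#' @param times_ms evaluation times in milliseconds.
#' @return Numeric vector of target values.
#' @export
make_target <- function(name, times_ms) {
  t <- times_ms / 1000
  switch(name,
         y1 = sin(12 * pi * t),
         y2 = sin(12 * pi * t) * sin(24 * pi * t),
         harmonics3 = (sin(12 * pi * t) + 0.5 * sin(24 * pi * t) +
                         0.25 * sin(36 * pi * t)) / 1.75,
         stop("make_target: unknown target '", name, "'", call. = FALSE))
}

#' Split filtered traces into train/test feature matrices
#'
#' Contiguous temporal split (training first, test second) of the
#' per-neuron filtered spike trains of a simulation record, optionally with
#' a constant bias column appended.
#'
#' @param record an \code{"snn_sim"} object.
#' @param train_fraction fraction of samples in the training block,
#'   strictly between 0 and 1.
#' @param bias append a constant column of ones.
#' @return List with matrices \code{X_train}, \code{X_test} and the
#'   corresponding \code{times_train}, \code{times_test} (ms).
#' @export
collect_features <- function(record, train_fraction = 0.5, bias = TRUE) {
  stopifnot(inherits(record, "snn_sim"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("collect_features: train_fraction must be in (0, 1)", call. = FALSE)
  X <- record$filtered
  n <- nrow(X)
  n_train <- floor(n * train_fraction)
  if (n_train < 10 || n - n_train < 10)
    stop("collect_features: fewer than 10 samples in a split", call. = FALSE)
  if (bias) X <- cbind(X, 1)
  idx <- seq_len(n_train)
  list(X_train = X[idx, , drop = FALSE],
       X_test = X[-idx, , drop = FALSE],
       times_train = record$trace_times[idx],
       times_test = record$trace_times[-idx])
}

#' Train a ridge readout in closed form
#'
#' Solves \code{argmin ||X phi - y||^2 + lambda ||phi||^2}. With
#' \code{lambda = 0} and rank-deficient \code{X} the minimum-norm
#' least-squares solution is returned and flagged.
#'
#' @param X feature matrix (time x features).
#' @param y target series (length \code{nrow(X)}).
#' @param lambda ridge penalty \code{>= 0}; \code{NULL} uses the default
#'   \code{1e-4 * trace(X'X) / ncol(X)}.
#' @return An object of class \code{"snn_readout"} with elements \code{phi},
#'   \code{lambda}, \code{mse_train}, \code{rank_deficient}.
#' @export
train_readout <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("train_readout: rows of X must match length of y", call. = FALSE)
  p <- ncol(X)
  G <- crossprod(X)
  if (is.null(lambda)) lambda <- 1e-4 * sum(diag(G)) / p
  if (lambda < 0) stop("train_readout: lambda must be >= 0", call. = FALSE)
  rank_def <- FALSE
  if (lambda == 0) {
    qrX <- qr(X)
    if (qrX$rank < p) {
      rank_def <- TRUE
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-12
      phi <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      phi <- drop(phi)
    } else {
      phi <- drop(qr.coef(qrX, y))
    }
  } else {
    phi <- drop(solve(G + diag(lambda, p), crossprod(X, y)))
  }
  fit <- drop(X %*% phi)
  out <- list(phi = phi, lambda = lambda,
              mse_train = mean((fit - y)^2),
              rank_deficient = rank_def, n_features = p)
  class(out) <- "snn_readout"
  out
}

#' Train a readout by one-sample recursive least squares
#'
#' Streams the rows of \code{X} through the classic RLS update with
#' \code{P0 = I / lambda}; algebraically identical to the batch ridge
#' solution of [train_readout()] after the full pass.
#'
#' @inheritParams train_readout
#' @param lambda ridge penalty \code{> 0}.
#' @return An \code{"snn_readout"} with the additional inverse-correlation
#'   matrix \code{P}.
#' @export
rls_readout <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (lambda <= 0) stop("rls_readout: lambda must be > 0", call. = FALSE)
  p <- ncol(X)
  P <- diag(1 / lambda, p)
  phi <- rep(0, p)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    Px <- P %*% x
    cc <- drop(1 / (1 + crossprod(x, Px)))
    e <- drop(crossprod(phi, x)) - y[i]
    phi <- phi - cc * e * drop(Px)
    P <- P - cc * tcrossprod(drop(Px))
  }
  fit <- drop(X %*% phi)
  out <- list(phi = phi, lambda = lambda, mse_train = mean((fit - y)^2),
              rank_deficient = FALSE, n_features = p, P = P)
  class(out) <- "snn_readout"
  out
}

#' @export
coef.snn_readout <- function(object, ...) object$phi

#' @export
predict.snn_readout <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$phi)
}

#' @export
print.snn_readout <- function(x, ...) {
  cat(sprintf("snn_readout: %d features, lambda = %.4g, train MSE = %.4g\n",
              x$n_features, x$lambda, x$mse_train))
  if (x$rank_deficient)
    cat("  note: rank-deficient design, minimum-norm solution\n")
  invisible(x)
}

#' Mean squared error of a readout on a dataset
#'
#' @param decoder an \code{"snn_readout"}.
#' @param X feature matrix.
#' @param y target series.
#' @return Scalar MSE.
#' @export
evaluate_readout <- function(decoder, X, y) {
  mean((predict(decoder, X) - y)^2)
}

#' Reservoir experiment: entrain, record, decode
#'
#' The curve-fitting pipeline. A train of brief global pulses at the
#' targets' fundamental frequency (6 Hz) entrains the network; after a
#' settling interval the per-neuron filtered traces are recorded, a ridge
#' readout is trained on the first block and scored on the held-out
#' continuation. Both benchmark targets are 6 Hz-periodic, so in the
#' entrained steady state the decoded output remains valid on the test
#' block; outside the responsive regimes (or without heterogeneity) the
#' features cannot support the fit and the test error stays near the
#' target variance.
#'
#' @inheritParams simulate_network
#' @param regime_eta mean external drive (pA); overrides
#'   \code{het$eta_bar}. The benchmark configuration places it just above
#'   the lower Hopf point, in the oscillatory regime.
#' @param stimulus drive specification; default a [make_pulse_train()] at
#'   6 Hz (amplitude 300 pA, width 60 ms) spanning the whole run.
#' @param target target name passed to [make_target()].
#' @param train_duration,test_duration length of the training and held-out
#'   blocks (ms).
#' @param settle initial interval discarded before decoding (ms).
#' @param lambda ridge penalty; the default is
#'   \code{lambda_scale * trace(X'X) / ncol(X)} on the training block.
#' @param lambda_scale relative ridge strength used when \code{lambda} is
#'   \code{NULL}.
#' @return An object of class \code{"rls_fit"}: \code{mse_train},
#'   \code{mse_test}, \code{var_train}, \code{var_test}, the decoder, and
#'   a config echo.
#' @export
run_rls_experiment <- function(params, het, n = 2000, regime_eta = NULL,
                               stimulus = NULL, target = "y1",
                               train_duration = 5000, test_duration = 2000,
                               settle = 2000, dt = 0.05, sample_every = 1,
                               lambda = NULL, lambda_scale = 1e-3,
                               seed = 1L) {
  stopifnot(inherits(params, "neuron_params"), inherits(het, "het_spec"))
  if (!is.null(regime_eta)) het$eta_bar <- regime_eta
  total <- settle + train_duration + test_duration
  if (is.null(stimulus))
    stimulus <- make_pulse_train(300, 60, 1000 / 6, duration = total)
  sim <- simulate_network(params, het, n, drive = stimulus,
                          duration = total, dt = dt,
                          sample_every = sample_every, seed = seed)
  keep <- sim$trace_times > settle
  sim$filtered <- sim$filtered[keep, , drop = FALSE]
  sim$trace_times <- sim$trace_times[keep]
  fs <- collect_features(sim, train_fraction =
                           train_duration / (train_duration + test_duration))
  y_train <- make_target(target, fs$times_train)
  y_test <- make_target(target, fs$times_test)
  if (is.null(lambda))
    lambda <- lambda_scale * sum(fs$X_train^2) / ncol(fs$X_train)
  dec <- train_readout(fs$X_train, y_train, lambda = lambda)
  out <- list(mse_train = dec$mse_train,
              mse_test = evaluate_readout(dec, fs$X_test, y_test),
              var_train = stats::var(y_train), var_test = stats::var(y_test),
              decoder = dec,
              config = list(n = n, eta_bar = het$eta_bar,
                            delta_eta = het$delta_eta, g_bar = het$g_bar,
                            delta_g = het$delta_g, theta_bar = het$theta_bar,
                            delta_theta = het$delta_theta, target = target,
                            train_duration = train_duration,
                            test_duration = test_duration, settle = settle,
                            dt = dt, sample_every = sample_every,
                            lambda = dec$lambda, seed = seed))
  class(out) <- "rls_fit"
  out
}

#' @export
print.rls_fit <- function(x, ...) {
  cat(sprintf("rls_fit (target %s, n = %d, eta_bar = %g pA)\n",
              x$config$target, x$config$n, x$config$eta_bar))
  cat(sprintf("  train MSE = %.4g (target var %.3g)\n", x$mse_train,
              x$var_train))
  cat(sprintf("  test  MSE = %.4g (target var %.3g)\n", x$mse_test,
              x$var_test))
  invisible(x)
}

#' Sweep one heterogeneity channel
#'
#' Repeats [run_rls_experiment()] over a grid of values of a single
#' heterogeneity parameter, with \code{n_seeds} independent networks per
#' value, and aggregates mean train/test MSE per value.
#'
#' @param channel one of \code{"eta"}, \code{"g"}, \code{"theta"} (the
#'   half-widths) or \code{"theta_bar"} (the reset-coefficient center).
#' @param values grid of channel values (widths \code{>= 0}; for
#'   \code{"theta_bar"}, centers in \code{[0, 1]}).
#' @param base named list of arguments for [run_rls_experiment()]
#'   (must contain \code{params} and \code{het}).
#' @param n_seeds networks per value (seeds \code{1 .. n_seeds} offset by
#'   \code{seed_offset}).
#' @param seed_offset added to each seed index.
#' @param csv optional path; when given the per-run table is written there
#'   and the aggregate next to it (suffix \code{_aggregate.csv}).
#' @return List with data.frames \code{runs} (channel, value, seed,
#'   mse_train, mse_test) and \code{aggregate} (mean MSEs per value).
#' @export
heterogeneity_sweep <- function(channel, values, base, n_seeds = 10,
                                seed_offset = 0, csv = NULL) {
  channel <- match.arg(channel, c("eta", "g", "theta", "theta_bar"))
  rows <- list()
  for (val in values) {
    het <- base$het
    if (channel == "eta") het$delta_eta <- val
    if (channel == "g") het$delta_g <- val
    if (channel == "theta") het$delta_theta <- val
    if (channel == "theta_bar") het$theta_bar <- val
    for (s in seq_len(n_seeds)) {
      args <- base
      args$het <- het
      args$seed <- s + seed_offset
      fit <- do.call(run_rls_experiment, args)
      rows[[length(rows) + 1]] <- data.frame(
        channel = channel, value = val, seed = s + seed_offset,
        mse_train = fit$mse_train, mse_test = fit$mse_test)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$value), function(d)
    data.frame(channel = channel, value = d$value[1],
               mse_train = mean(d$mse_train), mse_test = mean(d$mse_test),
               median_mse_test = stats::median(d$mse_test))))
  rownames(agg) <- NULL
  agg <- agg[order(agg$value), ]
  if (!is.null(csv)) {
    utils::write.csv(runs, csv, row.names = FALSE, quote = FALSE)
    utils::write.csv(agg, sub("\\.csv$", "_aggregate.csv", csv),
                     row.names = FALSE, quote = FALSE)
  }
  list(runs = runs, aggregate = agg)
}
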