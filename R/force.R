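#' Configuration for FORCE training
#'
#' FORCE replaces the gating-variable coupling with two recurrent current
#' pathways acting on the per-neuron filtered spike trains \code{r}:
#' a fixed sparse random matrix scaled by the gain \code{G}
#' (\code{G * (omega0 r)}, initializing the network in a fluctuation-driven
#' regime) and a learned rank-one feedback \code{Q * enc * (phi' r)} whose
#' decoder \code{phi} is trained online by recursive least squares. The
#' heterogeneity channels keep their meaning: \code{eta} is the per-neuron
#' bias current, \code{theta} the partial reset, and the network channel
#' acts as a per-neuron multiplicative gain \code{g_i / g_bar} on the
#' static recurrent current (center 1, relative width
#' \code{delta_g / g_bar}).
#'
#' The reported error is the log10 of the test MSE normalized by the
#' target's mean square power, so 0 marks the silence boundary: a network
#' whose output is no better than staying at zero scores \code{>= 0}
#' (failure), an accurate reconstruction scores well below 0.
#'
#' @param G gain of the static recurrent weights (\code{>= 0}).
#' @param Q coefficient of the learned feedback weights (\code{>= 0}).
#' @param n network size (\code{>= 2}).
#' @param p_static connection density of the static matrix, in
#'   \code{(0, 1]}.
#' @param rls_interval steps between decoder updates.
#' @param tau_rise rise time of the double-exponential synaptic filter used
#'   for the decoded traces (ms); the decay is the neuron preset's
#'   \code{tau_s}. Set to 0 for a first-order filter.
#' @param lambda_rls RLS regularization (initial \code{P = I / lambda}).
#' @param train_duration,test_duration training and autonomous test
#'   intervals (ms).
#' @param dt Euler step (ms).
#' @param target target name (see [make_target()]).
#' @param params a [neuron_params()] object.
#' @param het a [het_spec()] object; \code{het$eta_bar} is the mean bias
#'   current (default just above the quadratic-model rheobase
#'   \code{k ((v_t - v_r)/2)^2 = 1000} pA, where a homogeneous network is
#'   marginally active and its learning is fragile).
#' @param seed integer seed.
#' @return An object of class \code{"force_config"}.
#' @export
force_config <- function(G = 2e3, Q = 9e3, n = 1000, p_static = 0.1,
                         rls_interval = 50, tau_rise = 2, lambda_rls = 0.01,
                         train_duration = 5000, test_duration = 1000,
                         dt = 0.05, target = "y1",
                         params = ca3_params(),
                         het = het_spec(eta_bar = 1010, delta_eta = 0,
                                        g_bar = 15, delta_g = 0,
                                        theta_bar = 0, delta_theta = 0),
                         seed = 1L) {
  if (G < 0 || Q < 0) stop("force_config: G, Q must be >= 0", call. = FALSE)
  if (!(p_static > 0 && p_static <= 1))
    stop("force_config: p_static must be in (0, 1]", call. = FALSE)
  if (n < 2) stop("force_config: n must be >= 2", call. = FALSE)
  stopifnot(inherits(params, "neuron_params"), inherits(het, "het_spec"))
  if (tau_rise < 0 || tau_rise >= params$tau_s)
    stop("force_config: tau_rise must be in [0, tau_s)", call. = FALSE)
  cfg <- list(G = G, Q = Q, n = as.integer(n), p_static = p_static,
              rls_interval = as.integer(rls_interval), tau_rise = tau_rise,
              lambda_rls = lambda_rls, train_duration = train_duration,
              test_duration = test_duration, dt = dt, target = target,
              params = params, het = het, seed = as.integer(seed))
  class(cfg) <- "force_config"
  cfg
}

#' Initialize the FORCE network
#'
#' Samples the sparse static weight matrix (density \code{p_static},
#' entries zero-mean normal with variance \code{1 / (p_static * n)}), the
#' feedback encoders (uniform in \code{[-1, 1]}), the heterogeneity
#' channels, and the initial state.
#'
#' @param cfg a [force_config()] object.
#' @return List with \code{omega0} (n x n), \code{enc}, \code{eta},
#'   \code{theta}, \code{g_scale}, \code{v0}, \code{w0}.
#' @export
init_force <- function(cfg) {
  stopifnot(inherits(cfg, "force_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n; p <- cfg$p_static
  mask <- stats::runif(n * n) < p
  w <- stats::rnorm(n * n, 0, 1 / sqrt(p * n))
  omega0 <- matrix(ifelse(mask, w, 0), n, n)
  enc <- stats::runif(n, -1, 1)
  het <- cfg$het
  eta <- sample_lorentzian(n, het$eta_bar, het$delta_eta, het$eta_bounds)
  theta <- sample_lorentzian(n, het$theta_bar, het$delta_theta,
                             het$theta_bounds)
  if (het$delta_g > 0) {
    g <- sample_lorentzian(n, het$g_bar, het$delta_g, het$g_bounds)
    g_scale <- g / het$g_bar
  } else {
    g_scale <- rep(1, n)
  }
  v0 <- stats::runif(n, cfg$params$v_r, cfg$params$v_t)
  list(omega0 = omega0, enc = enc, eta = eta, theta = theta,
       g_scale = g_scale, v0 = v0, w0 = rep(0, n))
}

#' FORCE-train the spiking network on a target signal
#'
#' Runs the closed-loop simulation: during \code{train_duration} the
#' decoder is updated every \code{rls_interval} steps by recursive least
#' squares on the instantaneous error between the decoded output
#' \code{phi' r(t)} and the target; the decoder is then frozen and the
#' autonomous output scored on \code{test_duration}, yielding
#' \code{log10} of the test MSE normalized by the target's mean square.
#'
#' @param cfg a [force_config()] object.
#' @param target_series optional explicit target vector (one value per
#'   Euler step); by default the configured named target is evaluated on
#'   the step grid.
#' @param record_every record the error trace every this many steps.
#' @param return_P also return the final inverse-correlation matrix (for
#'   diagnostics; large).
#' @param record_rr also return the filtered-trace matrix sampled every
#'   \code{record_every} steps (diagnostics; large).
#' @return An object of class \code{"force_fit"}: \code{log_mse_test},
#'   \code{mse_test}, decoded \code{output} and \code{target} samples,
#'   error trace, decoder \code{phi}, spike count, and config echo.
#' @export
force_train <- function(cfg, target_series = NULL, record_every = 20L,
                        return_P = FALSE, record_rr = FALSE) {
  stopifnot(inherits(cfg, "force_config"))
  net <- init_force(cfg)
  n_train <- round(cfg$train_duration / cfg$dt)
  n_test <- round(cfg$test_duration / cfg$dt)
  if (is.null(target_series)) {
    times <- (seq_len(n_train + n_test)) * cfg$dt
    target_series <- make_target(cfg$target, times)
  }
  res <- cpp_force_run(net$v0, net$w0, net$eta, net$theta, net$g_scale,
                       unclass(cfg$params), net$omega0, net$enc,
                       cfg$G, cfg$Q, cfg$dt, cfg$tau_rise, as.integer(n_train),
                       as.integer(n_test), cfg$rls_interval,
                       cfg$lambda_rls, target_series,
                       as.integer(record_every), return_P, record_rr)
  test_idx <- (n_train + 1):(n_train + n_test)
  target_power <- mean(target_series[test_idx]^2)
  out <- list(log_mse_test = log10(res$mse_test / target_power),
              mse_test = res$mse_test, target_power = target_power,
              phi = res$phi, err_times = res$err_times,
              err_trace = res$err_trace, output = res$output,
              target = res$target, total_spikes = res$total_spikes,
              P = if (return_P) res$P else NULL,
              rr_trace = if (record_rr) res$rr_trace else NULL,
              config = cfg)
  class(out) <- "force_fit"
  out
}

#' @export
print.force_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("force_fit: n = %d, G = %g, Q = %g, target %s\n",
              cfg$n, cfg$G, cfg$Q, cfg$target))
  cat(sprintf("  train %g ms + test %g ms, %d spikes\n",
              cfg$train_duration, cfg$test_duration, x$total_spikes))
  cat(sprintf("  test MSE = %.4g (log10 = %.3f) -> %s\n", x$mse_test,
              x$log_mse_test,
              ifelse(x$log_mse_test < 0, "success", "failure")))
  invisible(x)
}

#' @export
plot.force_fit <- function(x, ...) {
  graphics::plot(x$err_times, x$target, type = "l", col = "grey",
                 xlab = "time (ms)", ylab = "output", ...)
  graphics::lines(x$err_times, x$output, col = "red")
  graphics::abline(v = x$config$train_duration, lty = 3)
  invisible(x)
}

#' Median log(MSE) over a (G, Q) grid
#'
#' Runs [force_train()] for every combination of static gain, feedback
#' gain, and heterogeneity setting, with \code{n_seeds} networks per cell,
#' and returns the per-cell median \code{log10} test MSE. A cell is
#' "viable" when the median log MSE is negative.
#'
#' @param cfg template [force_config()]; \code{G}, \code{Q}, \code{het} and
#'   \code{seed} are overridden per cell.
#' @param G_values,Q_values nonempty grids of hyperparameter values.
#' @param het_settings named list of [het_spec()] objects (one grid per
#'   setting).
#' @param n_seeds seeds per cell.
#' @param csv_dir optional directory: one CSV per setting (rows = G,
#'   columns = Q, cells = median log MSE) plus a JSON manifest.
#' @return data.frame with columns \code{setting}, \code{G}, \code{Q},
#'   \code{median_log_mse}, \code{viable}.
#' @export
gq_grid <- function(cfg, G_values, Q_values, het_settings, n_seeds = 3,
                    csv_dir = NULL) {
  stopifnot(inherits(cfg, "force_config"),
            length(G_values) > 0, length(Q_values) > 0)
  rows <- list()
  for (setting in names(het_settings)) {
    for (G in G_values) for (Q in Q_values) {
      lm <- numeric(n_seeds)
      for (s in seq_len(n_seeds)) {
        c2 <- cfg
        c2$G <- G; c2$Q <- Q; c2$het <- het_settings[[setting]]
        c2$seed <- cfg$seed + s - 1L
        fit <- force_train(c2)
        lm[s] <- fit$log_mse_test
      }
      rows[[length(rows) + 1]] <- data.frame(
        setting = setting, G = G, Q = Q,
        median_log_mse = stats::median(lm))
    }
  }
  out <- do.call(rbind, rows)
  out$viable <- out$median_log_mse < 0
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    for (setting in names(het_settings)) {
      d <- out[out$setting == setting, ]
      m <- matrix(d$median_log_mse, nrow = length(G_values),
                  ncol = length(Q_values), byrow = TRUE,
                  dimnames = list(paste0("G", G_values),
                                  paste0("Q", Q_values)))
      utils::write.csv(m, file.path(csv_dir, paste0("gq_", setting, ".csv")),
                       quote = FALSE)
    }
    jsonlite::write_json(
      list(settings = names(het_settings), n_seeds = n_seeds,
           seed0 = cfg$seed, G_values = G_values, Q_values = Q_values),
      file.path(csv_dir, "gq_manifest.json"), auto_unbox = TRUE)
  }
  out
}
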