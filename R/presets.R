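#' Read and write experiment configuration trees
#'
#' Configurations are plain named lists serialized as YAML or JSON
#' (selected by file extension); reading back a written config returns an
#' identical tree.
#'
#' @param config a named list.
#' @param path file path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @return \code{write_config}: the path, invisibly; \code{read_config}:
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else stop("write_config: use a .yaml or .json path", call. = FALSE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json") return(jsonlite::read_json(path, simplifyVector = TRUE))
  stop("read_config: use a .yaml or .json path", call. = FALSE)
}

#' Validate an experiment configuration tree
#'
#' Checks the physically meaningful constraints of a configuration list
#' (heterogeneity widths nonnegative, reset-coefficient support inside
#' \code{[0, 1]}, positive durations and steps, positive network sizes).
#'
#' @param config a named list; recognized fields are checked, unknown
#'   fields ignored.
#' @return \code{TRUE} if valid, otherwise a character vector of
#'   violations.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  for (nm in c("delta_eta", "delta_g", "delta_theta"))
    if (!is.null(config[[nm]]))
      chk(config[[nm]] < 0, paste0(nm, " must be >= 0"))
  if (!is.null(config$theta_bar))
    chk(config$theta_bar < 0 || config$theta_bar > 1,
        "theta_bar must be in [0, 1]")
  if (!is.null(config$theta_bounds))
    chk(config$theta_bounds[1] < 0 || config$theta_bounds[2] > 1,
        "theta_bounds must lie in [0, 1]")
  for (nm in c("duration", "train_duration", "test_duration", "dt",
               "steps", "n", "epochs", "batch_size"))
    if (!is.null(config[[nm]]))
      chk(config[[nm]] <= 0, paste0(nm, " must be > 0"))
  if (!is.null(config$p_static))
    chk(config$p_static <= 0 || config$p_static > 1,
        "p_static must be in (0, 1]")
  if (!is.null(config$train_fraction))
    chk(config$train_fraction <= 0 || config$train_fraction >= 1,
        "train_fraction must be in (0, 1)")
  if (length(v) == 0) TRUE else v
}

#' Names of the available experiment presets
#' @return Character vector of preset names.
#' @export
experiment_presets <- function() {
  c("fig1_bifurcation", "fig1_regime_mse", "fig2_rls_sweeps",
    "fig3_force_ablation", "fig4_gq_grid", "fig5_sgd_synthetic")
}

preset_log <- function(out_dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(msg)
}

#' Run a named experiment preset
#'
#' Each preset reproduces one figure-level pipeline at desk scale and
#' writes a config echo, CSV/JSON results, and a machine-readable summary
#' of its qualitative checks to \code{out_dir}. The exit value reflects
#' bookkeeping only; a failed qualitative check is recorded in the summary,
#' not raised as an error.
#'
#' @param name preset name (see [experiment_presets()]).
#' @param overrides named list of configuration overrides (merged over the
#'   preset defaults; unknown keys are rejected).
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress console messages.
#' @return Invisibly, the summary list written to
#'   \code{summary.json}.
#' @export
run_preset <- function(name, overrides = list(), seed = 1L,
                       out_dir = tempfile("preset_"), quiet = FALSE) {
  if (!name %in% experiment_presets())
    stop("run_preset: unknown preset '", name, "'. Available: ",
         paste(experiment_presets(), collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defaults <- preset_defaults(name)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("run_preset: unknown override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, overrides)
  val <- validate_config(cfg)
  if (!isTRUE(val))
    stop("run_preset: invalid config: ", paste(val, collapse = "; "),
         call. = FALSE)
  cfg$seed <- as.integer(seed)
  write_config(c(list(preset = name), cfg), file.path(out_dir, "config.json"))
  preset_log(out_dir, "preset ", name, " seed ", seed)
  summary <- switch(name,
    fig1_bifurcation = preset_fig1_bif(cfg, out_dir),
    fig1_regime_mse = preset_fig1_mse(cfg, out_dir),
    fig2_rls_sweeps = preset_fig2(cfg, out_dir),
    fig3_force_ablation = preset_fig3(cfg, out_dir),
    fig4_gq_grid = preset_fig4(cfg, out_dir),
    fig5_sgd_synthetic = preset_fig5(cfg, out_dir))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) {
    cat("preset", name, "->", out_dir, "\n")
    utils::str(summary, max.level = 2, give.attr = FALSE)
  }
  invisible(summary)
}

preset_defaults <- function(name) {
  switch(name,
    fig1_bifurcation = list(
      delta_eta = 1, g_bar = 15, eta_min = 800, eta_max = 1400,
      eta_step = 20, seed = 1L),
    fig1_regime_mse = list(
      n = 2000, g_bar = 15, dt = 0.05,
      eta_values = c(500, 1090, 1250), delta_values = c(1, 20, 20),
      targets = c("y1", "y2"), seed = 1L),
    fig2_rls_sweeps = list(
      n = 2000, g_bar = 15, dt = 0.05, eta_bar = 1090, n_seeds = 5,
      eta_widths = c(0, 1, 5, 20, 50, 200),
      g_widths = c(0, 1, 5, 10, 20, 50),
      theta_widths = c(0, 0.02, 0.05, 0.1),
      theta_bars = c(0, 0.25, 0.5, 0.75, 0.9), seed = 1L),
    fig3_force_ablation = list(
      n = 1000, G = 2e3, Q = 9e3, train_duration = 5000,
      test_duration = 1000, dt = 0.05, n_seeds = 10, eta_bar = 1010,
      delta_eta = 100, delta_g = 10, theta_bar = 0.9, delta_theta = 0.3,
      seed = 1L),
    fig4_gq_grid = list(
      n = 1000, G_values = c(1e3, 2e3, 3e3, 5e3),
      Q_values = c(2e3, 4.5e3, 9e3, 1.35e4), train_duration = 5000,
      test_duration = 1000, dt = 0.05, n_seeds = 1, eta_bar = 1010,
      delta_eta = 100, delta_g = 10, theta_bar = 0.9, delta_theta = 0.3,
      seed = 1L),
    fig5_sgd_synthetic = list(
      n_channels = 32, n_samples = 160, duration = 100, steps = 50,
      layer_sizes = 100, epochs = 15, jitter_sd = 12, n_seeds = 5,
      seed = 1L))
}

preset_fig1_bif <- function(cfg, out_dir) {
  params <- ca3_params()
  het <- het_spec(delta_eta = cfg$delta_eta, g_bar = cfg$g_bar)
  grid <- seq(cfg$eta_min, cfg$eta_max, by = cfg$eta_step)
  bif <- scan_bifurcation(params, het, grid)
  write_bifurcation(bif, file.path(out_dir, "bifurcation.csv"))
  probes <- if (length(bif$hopf) >= 2)
    c(bif$hopf[1] - 100, mean(bif$hopf[1:2]), bif$hopf[2] + 100)
  else c(cfg$eta_min, mean(grid), cfg$eta_max)
  labels <- vapply(probes, function(e)
    classify_regime(params, het, e)$label, character(1))
  list(hopf = bif$hopf, probe_eta = probes, probe_labels = labels,
       checks = list(
         two_hopf_points = length(bif$hopf) == 2,
         regime_order = identical(labels,
                                  c("quiescent", "oscillatory", "persistent"))))
}

preset_fig1_mse <- function(cfg, out_dir) {
  params <- ca3_params()
  rows <- list()
  for (i in seq_along(cfg$eta_values)) for (tg in cfg$targets) {
    het <- het_spec(eta_bar = cfg$eta_values[i],
                    delta_eta = cfg$delta_values[i], g_bar = cfg$g_bar)
    fit <- run_rls_experiment(params, het, n = cfg$n, target = tg,
                              dt = cfg$dt, seed = cfg$seed)
    rows[[length(rows) + 1]] <- data.frame(
      eta_bar = cfg$eta_values[i], delta_eta = cfg$delta_values[i],
      target = tg, mse_train = fit$mse_train,
      mse_test = fit$mse_test, var_test = fit$var_test)
  }
  d <- do.call(rbind, rows)
  utils::write.csv(d, file.path(out_dir, "regime_mse.csv"),
                   row.names = FALSE, quote = FALSE)
  lowest <- d[d$eta_bar == min(d$eta_bar), ]
  mid <- d[d$eta_bar == sort(unique(d$eta_bar))[2], ]
  list(table = d, checks = list(
    quiescent_fails = all(lowest$mse_test >= 0.5 * lowest$var_test),
    oscillatory_fits_y1 =
      any(mid$mse_test[mid$target == "y1"] <= 0.1 * mid$var_test[mid$target == "y1"])))
}

preset_fig2 <- function(cfg, out_dir) {
  params <- ca3_params()
  base <- list(params = params,
               het = het_spec(eta_bar = cfg$eta_bar, delta_eta = 0,
                              g_bar = cfg$g_bar),
               n = cfg$n, dt = cfg$dt, target = "y2")
  sweeps <- list(
    eta = heterogeneity_sweep("eta", cfg$eta_widths, base, cfg$n_seeds,
                              csv = file.path(out_dir, "sweep_eta.csv")),
    g = heterogeneity_sweep("g", cfg$g_widths, base, cfg$n_seeds,
                            csv = file.path(out_dir, "sweep_g.csv")),
    theta = {
      b2 <- base; b2$het$theta_bar <- 0.5
      heterogeneity_sweep("theta", cfg$theta_widths, b2, cfg$n_seeds,
                          csv = file.path(out_dir, "sweep_theta.csv"))
    },
    theta_bar = heterogeneity_sweep("theta_bar", cfg$theta_bars, base,
                                    cfg$n_seeds,
                                    csv = file.path(out_dir,
                                                    "sweep_theta_bar.csv")))
  ag <- sweeps$eta$aggregate
  dtheta <- sweeps$theta$aggregate
  sl <- stats::coef(stats::lm(mse_test ~ value, data = dtheta))[2]
  list(checks = list(
    heterogeneity_restores =
      ag$mse_test[ag$value == 0][1] > min(ag$mse_test[ag$value > 0]),
    delta_theta_slope = unname(sl)))
}

force_settings <- function(cfg) {
  list(
    homogeneous = het_spec(eta_bar = cfg$eta_bar, delta_eta = 0, g_bar = 15,
                           delta_g = 0, theta_bar = 0, delta_theta = 0),
    het_eta = het_spec(eta_bar = cfg$eta_bar, delta_eta = cfg$delta_eta,
                       g_bar = 15),
    het_g = het_spec(eta_bar = cfg$eta_bar, g_bar = 15,
                     delta_g = cfg$delta_g),
    het_theta = het_spec(eta_bar = cfg$eta_bar, theta_bar = cfg$theta_bar,
                         delta_theta = cfg$delta_theta),
    het_all = het_spec(eta_bar = cfg$eta_bar, delta_eta = cfg$delta_eta,
                       g_bar = 15, delta_g = cfg$delta_g,
                       theta_bar = cfg$theta_bar,
                       delta_theta = cfg$delta_theta))
}

preset_fig3 <- function(cfg, out_dir) {
  settings <- force_settings(cfg)
  rows <- list()
  for (nm in c("homogeneous", "het_eta", "het_g", "het_theta")) {
    for (s in seq_len(cfg$n_seeds)) {
      fc <- force_config(G = cfg$G, Q = cfg$Q, n = cfg$n,
                         train_duration = cfg$train_duration,
                         test_duration = cfg$test_duration, dt = cfg$dt,
                         het = settings[[nm]], seed = cfg$seed + s - 1L)

      fit <- force_train(fc)
      rows[[length(rows) + 1]] <- data.frame(
        setting = nm, seed = fc$seed, log_mse = fit$log_mse_test)
    }
  }
  d <- do.call(rbind, rows)
  utils::write.csv(d, file.path(out_dir, "force_ablation.csv"),
                   row.names = FALSE, quote = FALSE)
  ok <- function(nm) mean(d$log_mse[d$setting == nm] < 0)
  list(success_fraction = sapply(unique(d$setting), ok),
       checks = list(
         homogeneous_fails = ok("homogeneous") < 0.5,
         each_heterogeneity_restores =
           all(sapply(c("het_eta", "het_g", "het_theta"), ok) >= 0.7)))
}

preset_fig4 <- function(cfg, out_dir) {
  settings <- force_settings(cfg)
  fc <- force_config(n = cfg$n, train_duration = cfg$train_duration,
                     test_duration = cfg$test_duration, dt = cfg$dt,
                     seed = cfg$seed)
  grid <- gq_grid(fc, cfg$G_values, cfg$Q_values, settings,
                  n_seeds = cfg$n_seeds, csv_dir = out_dir)
  viable <- tapply(grid$viable, grid$setting, sum)
  list(viable_cells = as.list(viable), checks = list(
    full_heterogeneity_widest =
      viable[["het_all"]] >= max(viable[names(viable) != "het_all"])))
}

sgd_het_conditions <- function() {
  # operating point near rheobase: units act as coincidence detectors;
  # the heterogeneous condition disperses distance-to-threshold, input
  # gain and the partial reset (effective here because dt = 1 ms gives
  # substantial spike overshoot)
  list(hom = het_spec(eta_bar = 900, delta_eta = 0, g_bar = 1,
                      theta_bar = 0, delta_theta = 0),
       het = het_spec(eta_bar = 900, delta_eta = 30, g_bar = 1,
                      delta_g = 0.15, theta_bar = 0.2, delta_theta = 0.05,
                      eta_bounds = c(650, 980), g_bounds = c(0.2, 2.5)))
}

preset_fig5 <- function(cfg, out_dir) {
  ds <- make_temporal_task(n_classes = 2, n_channels = cfg$n_channels,
                           n_samples = cfg$n_samples,
                           duration = cfg$duration,
                           jitter_sd = cfg$jitter_sd, seed = cfg$seed)
  conds <- sgd_het_conditions()
  accs <- list(hom = numeric(cfg$n_seeds), het = numeric(cfg$n_seeds))
  for (s in seq_len(cfg$n_seeds)) {
    for (mode in c("hom", "het")) {
      sc <- sgd_config(n_in = cfg$n_channels, n_classes = 2,
                       layer_sizes = cfg$layer_sizes, steps = cfg$steps,
                       epochs = cfg$epochs, w_scale = 8000,
                       het = conds[[mode]], seed = cfg$seed + s - 1L)
      accs[[mode]][s] <- train_sgd(sc, ds)$final_test_accuracy
    }
  }
  utils::write.csv(data.frame(seed = seq_len(cfg$n_seeds),
                              hom = accs$hom, het = accs$het),
                   file.path(out_dir, "sgd_accuracy.csv"),
                   row.names = FALSE, quote = FALSE)
  list(mean_hom = mean(accs$hom), mean_het = mean(accs$het),
       checks = list(het_at_least_hom = mean(accs$het) >= mean(accs$hom)))
}
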