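#' Initialize a heterogeneous all-to-all network
#'
#' Samples the three per-neuron heterogeneity channels (external drive
#' \code{eta}, coupling gain \code{g}, partial-reset coefficient
#' \code{theta}) from their Lorentzian distributions, disperses the initial
#' membrane potentials uniformly between rest and threshold to break
#' symmetry, and zeroes the recovery and gating variables.
#'
#' @param params a [neuron_params()] object.
#' @param het a [het_spec()] object.
#' @param n number of neurons (\code{>= 1}).
#' @param seed integer seed; the state is a pure function of the arguments.
#'
#' @return An object of class \code{"network_state"}: list with vectors
#'   \code{v}, \code{w}, \code{eta}, \code{g}, \code{theta}, scalar gating
#'   variable \code{s}, time \code{t} (ms) and size \code{n}.
#' @export
init_network <- function(params, het, n, seed = 1L) {
  stopifnot(inherits(params, "neuron_params"), inherits(het, "het_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("init_network: n must be a count >= 1", call. = FALSE)
  n <- as.integer(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eta <- sample_lorentzian(n, het$eta_bar, het$delta_eta, het$eta_bounds)
  g <- sample_lorentzian(n, het$g_bar, het$delta_g, het$g_bounds)
  theta <- sample_lorentzian(n, het$theta_bar, het$delta_theta,
                             het$theta_bounds)
  v <- stats::runif(n, params$v_r, params$v_t)
  st <- list(v = v, w = rep(0, n), s = 0, eta = eta, g = g, theta = theta,
             t = 0, n = n)
  class(st) <- "network_state"
  st
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("network_state: %d neurons at t = %g ms\n", x$n, x$t))
  cat(sprintf("  v in [%.2f, %.2f] mV, s = %.4g\n", min(x$v), max(x$v), x$s))
  cat(sprintf("  eta in [%.3g, %.3g] pA; g in [%.3g, %.3g] nS; theta in [%.3g, %.3g]\n",
              min(x$eta), max(x$eta), min(x$g), max(x$g),
              min(x$theta), max(x$theta)))
  invisible(x)
}

#' Partial post-spike reset
#'
#' Applies the partial reset rule \code{v_reset + theta * (v - v_peak)} to a
#' membrane potential at or above the spike cutoff. \code{theta = 0} is a
#' full reset to \code{v_reset}; \code{theta > 0} retains a fraction of the
#' overshoot.
#'
#' @param v_above membrane potential(s) at or above \code{v_peak} (mV).
#' @param theta reset coefficient(s) in \code{[0, 1]} (recycled).
#' @param params a [neuron_params()] object.
#' @return Reset membrane potential(s) (mV).
#' @export
apply_reset <- function(v_above, theta, params) {
  stopifnot(inherits(params, "neuron_params"))
  if (any(v_above < params$v_peak))
    stop("apply_reset: v_above must be >= v_peak", call. = FALSE)
  params$v_reset + theta * (v_above - params$v_peak)
}

#' Advance the network one Euler step
#'
#' Reference (pure R) single-step update: forward-Euler integration of the
#' voltage and recovery equations with input \code{eta_i + I_ext + g_i s (E
#' - v_i)}, exact exponential decay of the gating variable, then
#' threshold-and-reset with the partial reset rule. Each spike increments
#' the gating variable by \code{s_jump / n}. The compiled simulator in
#' [simulate_network()] performs the identical update; this function is the
#' readable reference used for small networks and for testing.
#'
#' @param state a \code{"network_state"}.
#' @param params a [neuron_params()] object.
#' @param I_ext global external drive during the step (pA).
#' @param dt time step (ms), \code{> 0}.
#' @return List with the advanced \code{state} and \code{spiked}, the
#'   integer indices of neurons that spiked during the step.
#' @export
step_network <- function(state, params, I_ext = 0, dt = 0.05) {
  stopifnot(inherits(state, "network_state"), inherits(params, "neuron_params"))
  if (dt <= 0) stop("step_network: dt must be > 0", call. = FALSE)
  p <- params
  v <- state$v; w <- state$w; s <- state$s
  I <- state$eta + I_ext + state$g * s * (p$E - v)
  v_new <- v + dt * (p$k * (v - p$v_r) * (v - p$v_t) - w + I) / p$C
  w_new <- w + dt * (p$beta * (v - p$v_r) - w) / p$tau_w
  s_new <- s * exp(-dt / p$tau_s)
  spiked <- which(v_new >= p$v_peak)
  if (any(!is.finite(v_new)))
    stop(sprintf("step_network: non-finite membrane potential at t = %g ms",
                 state$t), call. = FALSE)
  if (length(spiked)) {
    # retained membrane cannot exceed the cutoff (guards the runaway
    # ratchet of large retained overshoots when theta is close to 1)
    v_new[spiked] <- pmin(apply_reset(v_new[spiked], state$theta[spiked], p),
                          p$v_peak)
    w_new[spiked] <- w_new[spiked] + p$w_jump
    s_new <- s_new + length(spiked) * p$s_jump / state$n
  }
  state$v <- v_new; state$w <- w_new; state$s <- s_new
  state$t <- state$t + dt
  list(state = state, spiked = spiked)
}

# Evaluate a drive specification on a vector of times (ms).
# Accepts: NULL or scalar (constant), a function of t, a pulse created by
# make_pulse(), or a list of pulses (additive composition).
eval_drive <- function(drive, times) {
  if (is.null(drive)) return(rep(0, length(times)))
  if (is.numeric(drive) && length(drive) == 1L) return(rep(drive, length(times)))
  if (is.function(drive)) return(vapply(times, drive, numeric(1)))
  if (inherits(drive, "drive_pulse")) {
    return(ifelse(times >= drive$onset & times < drive$onset + drive$width,
                  drive$amplitude, 0))
  }
  if (is.list(drive)) {
    out <- rep(0, length(times))
    for (d in drive) out <- out + eval_drive(d, times)
    return(out)
  }
  stop("unrecognized drive specification", call. = FALSE)
}

#' Simulate the heterogeneous coupled network
#'
#' Runs the all-to-all coupled Izhikevich network by forward Euler,
#' recording the spike raster, the gating variable, the applied drive, and
#' the per-neuron exponentially filtered spike trains (unit-area kernel
#' with time constant \code{tau_s}) sampled on a regular grid. The filtered
#' traces are the feature matrix used by the readout stages; their
#' steady-state value equals a neuron's firing rate in kHz.
#'
#' @inheritParams init_network
#' @param drive global time-varying drive: \code{NULL}, a scalar, a function
#'   of time (ms), a [make_pulse()] object or a list of pulses.
#' @param duration simulation length (ms), \code{> 0}.
#' @param dt Euler step (ms); must divide \code{sample_every}.
#' @param sample_every trace sampling interval (ms).
#' @param record_v,record_w record full per-neuron state traces (memory!).
#' @param state optional pre-built \code{"network_state"} (overrides
#'   \code{het}, \code{n}, \code{seed} sampling).
#'
#' @return An object of class \code{"snn_sim"}: list with \code{raster}
#'   (data.frame \code{time_ms}, \code{neuron}), \code{trace_times},
#'   \code{filtered} (time x N matrix), \code{s_trace}, \code{drive},
#'   optional \code{v_trace}/\code{w_trace}, the final state, and the
#'   configuration echo.
#' @export
simulate_network <- function(params, het = NULL, n = NULL, drive = NULL,
                             duration, dt = 0.05, sample_every = 1,
                             record_v = FALSE, record_w = FALSE,
                             seed = 1L, state = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.numeric(duration) || duration <= 0)
    stop("simulate_network: duration must be > 0", call. = FALSE)
  if (dt <= 0) stop("simulate_network: dt must be > 0", call. = FALSE)
  steps_per_sample <- round(sample_every / dt)
  if (abs(steps_per_sample * dt - sample_every) > 1e-9 * sample_every)
    stop("simulate_network: dt must divide sample_every", call. = FALSE)
  if (is.null(state)) {
    if (is.null(het) || is.null(n))
      stop("simulate_network: provide either a state or (het, n)", call. = FALSE)
    state <- init_network(params, het, n, seed = seed)
  }
  n_steps <- round(duration / dt)
  step_times <- state$t + (seq_len(n_steps) - 1L) * dt
  drv <- eval_drive(drive, step_times)
  res <- cpp_simulate_net(state$v, state$w, state$s, state$eta, state$g,
                          state$theta, unclass(params), drv, dt,
                          as.integer(n_steps), as.integer(steps_per_sample),
                          record_v, record_w, state$t)
  final <- state
  final$v <- res$v_end; final$w <- res$w_end; final$s <- res$s_end
  final$t <- state$t + n_steps * dt
  out <- list(
    raster = data.frame(time_ms = res$spike_times, neuron = res$spike_ids),
    trace_times = res$trace_times,
    filtered = res$filtered,
    s_trace = res$s_trace,
    drive = res$drive,
    v_trace = if (record_v) res$v_trace else NULL,
    w_trace = if (record_w) res$w_trace else NULL,
    state = final,
    n = state$n, duration = duration, dt = dt,
    sample_every = sample_every, seed = seed, t0 = state$t)
  class(out) <- "snn_sim"
  out
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf("snn_sim: %d neurons, %g ms at dt = %g ms\n",
              x$n, x$duration, x$dt))
  cat(sprintf("  %d spikes (%.3g Hz per neuron)\n", nrow(x$raster),
              1000 * nrow(x$raster) / (x$n * x$duration)))
  cat(sprintf("  traces: %d samples every %g ms\n",
              length(x$trace_times), x$sample_every))
  invisible(x)
}

#' @export
plot.snn_sim <- function(x, max_neurons = 200, ...) {
  r <- x$raster
  if (x$n > max_neurons) r <- r[r$neuron <= max_neurons, ]
  graphics::plot(r$time_ms, r$neuron, pch = ".", cex = 2,
                 xlab = "time (ms)", ylab = "neuron", ...)
  invisible(x)
}

#' Windowed population firing rate
#'
#' Partitions the simulation interval into consecutive windows and returns
#' the spike count per window divided by \code{N * window}, i.e. the
#' population rate in kHz per neuron.
#'
#' @param record an \code{"snn_sim"} object.
#' @param window window length (ms), \code{> 0} and at most the record
#'   duration.
#' @return data.frame with window midpoints \code{time_ms} and \code{rate}
#'   (kHz per neuron).
#' @export
population_rate <- function(record, window) {
  stopifnot(inherits(record, "snn_sim"))
  if (!is.numeric(window) || window <= 0)
    stop("population_rate: window must be > 0", call. = FALSE)
  if (window > record$duration)
    stop("population_rate: window longer than the record", call. = FALSE)
  edges <- seq(record$t0, record$t0 + record$duration, by = window)
  if (edges[length(edges)] < record$t0 + record$duration)
    edges <- c(edges, record$t0 + record$duration)
  cnt <- graphics::hist(record$raster$time_ms, breaks = edges,
                        plot = FALSE)$counts
  widths <- diff(edges)
  data.frame(time_ms = (edges[-length(edges)] + edges[-1]) / 2,
             rate = cnt / (record$n * widths))
}

#' Export / import a spike raster as CSV
#'
#' Two-column CSV (\code{time_ms}, \code{neuron_id}) with a header row.
#'
#' @param record an \code{"snn_sim"} object (or a raster data.frame).
#' @param path output file path.
#' @return \code{write_raster}: the path, invisibly. \code{read_raster}:
#'   a data.frame with columns \code{time_ms}, \code{neuron}.
#' @export
write_raster <- function(record, path) {
  r <- if (inherits(record, "snn_sim")) record$raster else record
  utils::write.csv(data.frame(time_ms = r$time_ms, neuron_id = r$neuron),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  d <- utils::read.csv(path)
  data.frame(time_ms = d$time_ms, neuron = d$neuron_id)
}

#' Export state traces as wide CSV
#'
#' Writes the filtered traces (and gating variable) with a leading
#' \code{time_ms} column.
#'
#' @param record an \code{"snn_sim"} object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_traces <- function(record, path) {
  stopifnot(inherits(record, "snn_sim"))
  d <- data.frame(time_ms = record$trace_times, s = record$s_trace)
  f <- as.data.frame(record$filtered)
  names(f) <- paste0("r", seq_len(ncol(f)))
  utils::write.csv(cbind(d, f), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
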