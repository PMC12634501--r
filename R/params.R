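#' Biophysical constants of the Izhikevich neuron
#'
#' Bundles the shared (non-heterogeneous) parameters of the adaptive
#' quadratic integrate-and-fire (Izhikevich) neuron used throughout the
#' package: quadratic voltage dynamics with a slow recovery variable,
#' spike cutoff at \code{v_peak} and a partial post-spike reset.
#'
#' @param C membrane capacitance (pF).
#' @param k leakage/gain parameter of the quadratic term (nS/mV).
#' @param v_r resting potential (mV).
#' @param v_t threshold-like potential (mV).
#' @param E synaptic reversal potential (mV).
#' @param tau_w recovery-variable time constant (ms).
#' @param beta coupling of the recovery variable to voltage (nS).
#' @param v_peak spike cutoff (mV).
#' @param v_reset reset base potential (mV).
#' @param w_jump spike-triggered adaptation increment (pA).
#' @param tau_s synaptic decay time constant (ms).
#' @param s_jump synaptic coupling increment per spike (dimensionless).
#'
#' @return An object of class \code{"neuron_params"} (a validated named list).
#' @seealso [ca3_params()] for the default pyramidal-cell preset.
#' @export
neuron_params <- function(C = 250, k = 2.5, v_r = -60, v_t = -20, E = 0,
                          tau_w = 100, beta = 0, v_peak = 30, v_reset = -65,
                          w_jump = 200, tau_s = 20, s_jump = 1) {
  p <- list(C = C, k = k, v_r = v_r, v_t = v_t, E = E, tau_w = tau_w,
            beta = beta, v_peak = v_peak, v_reset = v_reset,
            w_jump = w_jump, tau_s = tau_s, s_jump = s_jump)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron_params: '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (p$C <= 0) stop("neuron_params: C must be > 0", call. = FALSE)
  if (p$tau_w <= 0) stop("neuron_params: tau_w must be > 0", call. = FALSE)
  if (p$tau_s <= 0) stop("neuron_params: tau_s must be > 0", call. = FALSE)
  if (!(p$v_r < p$v_t && p$v_t < p$v_peak))
    stop("neuron_params: require v_r < v_t < v_peak", call. = FALSE)
  if (p$v_reset >= p$v_peak)
    stop("neuron_params: require v_reset < v_peak", call. = FALSE)
  class(p) <- "neuron_params"
  p
}

#' Default pyramidal-cell parameter preset
#'
#' A published Izhikevich parameter set for hippocampal pyramidal cells
#' (capacitance 250 pF, gain 2.5 nS/mV, rest -60 mV, threshold -20 mV,
#' cutoff 30 mV, reset -65 mV, adaptation time constant 100 ms, adaptation
#' jump 200 pA, synaptic decay 20 ms). With the default coupling center
#' \code{g_bar = 15} nS this preset exhibits the three dynamical regimes of
#' the mean-field reduction (quiescent, oscillatory, persistently active)
#' as the mean drive increases.
#'
#' @param ... overrides passed to [neuron_params()].
#' @return A \code{"neuron_params"} object.
#' @export
ca3_params <- function(...) {
  args <- list(...)
  do.call(neuron_params, args)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Izhikevich neuron parameters\n")
  cat(sprintf("  C = %g pF, k = %g nS/mV, v_r = %g mV, v_t = %g mV, E = %g mV\n",
              x$C, x$k, x$v_r, x$v_t, x$E))
  cat(sprintf("  tau_w = %g ms, beta = %g nS, w_jump = %g pA\n",
              x$tau_w, x$beta, x$w_jump))
  cat(sprintf("  v_peak = %g mV, v_reset = %g mV (partial reset per neuron)\n",
              x$v_peak, x$v_reset))
  cat(sprintf("  tau_s = %g ms, s_jump = %g\n", x$tau_s, x$s_jump))
  invisible(x)
}

#' Heterogeneity specification for the three Lorentzian channels
#'
#' Describes the per-neuron parameter distributions: external drive
#' \code{eta}, recurrent coupling gain \code{g}, and the partial-reset
#' coefficient \code{theta}. Each channel is Lorentzian (Cauchy) with a
#' center and a half-width-at-half-maximum; physically bounded channels
#' are sampled by rejection so the Lorentzian shape is preserved on the
#' support.
#'
#' @param eta_bar center of the external-current distribution (pA).
#' @param delta_eta half-width of the external-current distribution (pA).
#' @param g_bar center of the coupling-gain distribution (nS).
#' @param delta_g half-width of the coupling-gain distribution (nS).
#' @param theta_bar center of the partial-reset coefficient (dimensionless,
#'   in \code{[0, 1]}; 0 is a full reset).
#' @param delta_theta half-width of the reset-coefficient distribution.
#' @param eta_bounds optional closed support interval for eta (default
#'   unbounded).
#' @param g_bounds support interval for g; must lie in \code{[0, Inf)}.
#' @param theta_bounds support interval for theta; must lie in \code{[0, 1]}.
#'
#' @return An object of class \code{"het_spec"}.
#' @export
het_spec <- function(eta_bar = 1100, delta_eta = 1,
                     g_bar = 15, delta_g = 0,
                     theta_bar = 0, delta_theta = 0,
                     eta_bounds = NULL, g_bounds = c(0, Inf),
                     theta_bounds = c(0, 1)) {
  h <- list(eta_bar = eta_bar, delta_eta = delta_eta,
            g_bar = g_bar, delta_g = delta_g,
            theta_bar = theta_bar, delta_theta = delta_theta,
            eta_bounds = eta_bounds, g_bounds = g_bounds,
            theta_bounds = theta_bounds)
  for (nm in c("eta_bar", "delta_eta", "g_bar", "delta_g",
               "theta_bar", "delta_theta")) {
    if (!is.numeric(h[[nm]]) || length(h[[nm]]) != 1L || !is.finite(h[[nm]]))
      stop("het_spec: '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (h$delta_eta < 0 || h$delta_g < 0 || h$delta_theta < 0)
    stop("het_spec: half-widths must be >= 0", call. = FALSE)
  chk_bounds <- function(b, lo, hi, nm) {
    if (is.null(b)) return(invisible())
    if (length(b) != 2L || b[1] >= b[2])
      stop("het_spec: '", nm, "' must be an increasing interval", call. = FALSE)
    if (b[1] < lo || b[2] > hi)
      stop("het_spec: '", nm, "' must lie within [", lo, ", ", hi, "]",
           call. = FALSE)
  }
  chk_bounds(h$g_bounds, 0, Inf, "g_bounds")
  chk_bounds(h$theta_bounds, 0, 1, "theta_bounds")
  chk_bounds(h$eta_bounds, -Inf, Inf, "eta_bounds")
  if (!is.null(h$theta_bounds) &&
      (h$theta_bar < h$theta_bounds[1] || h$theta_bar > h$theta_bounds[2]))
    stop("het_spec: theta_bar outside theta_bounds", call. = FALSE)
  if (!is.null(h$g_bounds) && (h$g_bar < h$g_bounds[1] || h$g_bar > h$g_bounds[2]))
    stop("het_spec: g_bar outside g_bounds", call. = FALSE)
  class(h) <- "het_spec"
  h
}

#' @export
print.het_spec <- function(x, ...) {
  cat("Heterogeneity specification (Lorentzian channels)\n")
  cat(sprintf("  eta:   center %g pA, half-width %g pA\n", x$eta_bar, x$delta_eta))
  cat(sprintf("  g:     center %g nS, half-width %g nS, support [%g, %g]\n",
              x$g_bar, x$delta_g, x$g_bounds[1], x$g_bounds[2]))
  cat(sprintf("  theta: center %g, half-width %g, support [%g, %g]\n",
              x$theta_bar, x$delta_theta, x$theta_bounds[1], x$theta_bounds[2]))
  invisible(x)
}

#' Homogeneous control specification
#'
#' Convenience constructor for the no-heterogeneity control condition:
#' all half-widths zero and a full reset (\code{theta_bar = 0}).
#'
#' @param eta_bar mean external drive (pA).
#' @param g_bar coupling gain (nS).
#' @param ... further overrides passed to [het_spec()].
#' @return A \code{"het_spec"} object.
#' @export
homogeneous_spec <- function(eta_bar = 1100, g_bar = 15, ...) {
  het_spec(eta_bar = eta_bar, delta_eta = 0, g_bar = g_bar, delta_g = 0,
           theta_bar = 0, delta_theta = 0, ...)
}
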