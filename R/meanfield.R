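#' Right-hand side of the mean-field reduction
#'
#' Four-dimensional Lorentzian-ansatz reduction of the heterogeneous
#' network in the limit of infinitely many neurons with Lorentzian external
#' drive (width \code{delta_eta}) and homogeneous coupling gain and reset.
#' Writing the voltage equation as \code{dv/dt = a v^2 + b v + c} with
#' \code{a = k/C}, \code{b = -(k (v_r + v_t) + g s)/C} and
#' \code{c = (k v_r v_t - w + eta_bar + I_ext + g s E)/C}, the
#' characteristic \code{z = v_bar + i pi C r / k} obeys
#' \code{dz/dt = a z^2 + b z + c + i delta_eta / C}. Splitting into real
#' and imaginary parts and appending the adaptation and gating equations
#' gives the four rates returned here (state order \code{r, v_bar, w_bar,
#' s}; \code{r} in kHz, times in ms).
#'
#' The reduction is derived for heterogeneity in the drive only, with a
#' full reset and infinite spike cutoffs; it is used with the network's
#' finite cutoffs, so a systematic finite-size/finite-cutoff bias of order
#' a few percent is expected when comparing against simulations.
#'
#' @param state numeric length-4 vector \code{c(r, v_bar, w_bar, s)}.
#' @param params a [neuron_params()] object.
#' @param het a [het_spec()] object; \code{delta_g} and \code{delta_theta}
#'   must be zero for the reduction to apply.
#' @param I_ext additional global drive (pA).
#' @return Numeric length-4 vector of time derivatives.
#' @export
meanfield_rhs <- function(state, params, het, I_ext = 0) {
  stopifnot(inherits(params, "neuron_params"), inherits(het, "het_spec"))
  if (het$delta_g != 0 || het$delta_theta != 0)
    stop("meanfield_rhs: reduction requires delta_g = delta_theta = 0",
         call. = FALSE)
  r <- state[1]; v <- state[2]; w <- state[3]; s <- state[4]
  if (r < 0) stop("meanfield_rhs: negative firing rate", call. = FALSE)
  p <- params; g <- het$g_bar
  dr <- (p$k / p$C) * r * (2 * v - p$v_r - p$v_t) - (g * s / p$C) * r +
    het$delta_eta * p$k / (pi * p$C^2)
  dv <- (p$k * (v - p$v_r) * (v - p$v_t) + g * s * (p$E - v) - w +
           het$eta_bar + I_ext) / p$C - (pi^2 * p$C / p$k) * r^2
  dw <- (p$beta * (v - p$v_r) - w) / p$tau_w + p$w_jump * r
  ds <- -s / p$tau_s + p$s_jump * r
  c(dr, dv, dw, ds)
}

#' Integrate the mean-field equations
#'
#' Adaptive integration (deSolve, \code{lsoda}) of the four-dimensional
#' reduction. The rate component is floored at zero before evaluating the
#' rhs to keep the adaptive stepper inside the physical domain (the floor
#' only matters when \code{delta_eta = 0}, where \code{r = 0} is invariant
#' but roundoff can graze negative values).
#'
#' @param initial length-4 state \code{c(r, v_bar, w_bar, s)}.
#' @inheritParams meanfield_rhs
#' @param drive drive specification (see [simulate_network()]).
#' @param duration integration length (ms).
#' @param dt output sampling interval (ms).
#' @return data.frame with columns \code{time}, \code{r}, \code{v_bar},
#'   \code{w_bar}, \code{s}.
#' @export
integrate_meanfield <- function(initial, params, het, drive = NULL,
                                duration, dt = 0.5) {
  stopifnot(length(initial) == 4, duration > 0)
  f <- function(t, x, parms) {
    x[1] <- max(x[1], 0)
    list(meanfield_rhs(x, params, het, I_ext = eval_drive(drive, t)))
  }
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y = c(r = initial[1], v_bar = initial[2],
                            w_bar = initial[3], s = initial[4]),
                      times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (any(!is.finite(out[, -1])))
    stop("integrate_meanfield: non-finite trajectory (blowup)", call. = FALSE)
  d <- as.data.frame(out)
  names(d)[1] <- "time"
  d
}

# Central finite-difference Jacobian of the mean-field rhs, step 1e-6 in
# scaled units (each coordinate scaled by max(|x_i|, 1)).
mf_jacobian <- function(state, params, het, h = 1e-6) {
  J <- matrix(0, 4, 4)
  sc <- pmax(abs(state), 1)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h * sc[j]
    xp <- state + e; xm <- state - e
    xp[1] <- max(xp[1], 0); xm[1] <- max(xm[1], 0)
    J[, j] <- (meanfield_rhs(xp, params, het) -
                 meanfield_rhs(xm, params, het)) / (xp[j] - xm[j])
  }
  J
}

# Newton iteration on the 4-D rhs from one initial guess; NULL on failure.
mf_newton <- function(x0, params, het, tol = 1e-10, maxit = 100) {
  x <- x0
  for (it in seq_len(maxit)) {
    x[1] <- max(x[1], 0)
    fx <- meanfield_rhs(x, params, het)
    if (max(abs(fx)) < tol) break
    J <- mf_jacobian(x, params, het)
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    # damped step to avoid overshooting into r < 0
    lam <- 1
    while (x[1] + lam * dx[1] < 0 && lam > 1e-6) lam <- lam / 2
    x <- x + lam * dx
    if (any(!is.finite(x))) return(NULL)
  }
  x[1] <- max(x[1], 0)
  if (max(abs(meanfield_rhs(x, params, het))) > 1e-8) return(NULL)
  x
}

#' Fixed points of the mean-field reduction
#'
#' Finds roots of the four-dimensional rhs by damped Newton iteration from
#' several seeded initial guesses (plus any user guesses), merges
#' duplicates, and classifies stability from the eigenvalues of a central
#' finite-difference Jacobian.
#'
#' @inheritParams meanfield_rhs
#' @param eta_bar mean external drive (pA); overrides \code{het$eta_bar}.
#' @param guesses optional list of extra length-4 initial guesses.
#' @return List of fixed points, each a list with \code{state} (length-4),
#'   \code{stable} (logical), \code{eigenvalues} (complex), and
#'   \code{oscillatory} (leading eigenvalue pair complex). Empty list if no
#'   root is found.
#' @export
find_fixed_points <- function(params, het, eta_bar = het$eta_bar,
                              guesses = NULL) {
  het$eta_bar <- eta_bar
  p <- params
  base <- list(
    c(1e-5, p$v_r, 0, 1e-4),
    c(1e-3, (p$v_r + p$v_t) / 2, 0.1, 0.02),
    c(5e-3, (p$v_r + p$v_t) / 2, 1, 0.1),
    c(0.02, p$v_t, 4, 0.4),
    c(0.05, p$v_t, 10, 1))
  guesses <- c(base, guesses)
  roots <- list()
  for (x0 in guesses) {
    x <- mf_newton(x0, params, het)
    if (is.null(x) || x[1] < 0) next
    dup <- FALSE
    for (rt in roots) {
      if (max(abs(rt$state - x) / pmax(abs(rt$state), 1e-3)) < 1e-5) {
        dup <- TRUE; break
      }
    }
    if (dup) next
    ev <- eigen(mf_jacobian(x, params, het), only.values = TRUE)$values
    ord <- order(Re(ev), decreasing = TRUE)
    ev <- ev[ord]
    roots[[length(roots) + 1]] <- list(
      state = x, stable = max(Re(ev)) < 0, eigenvalues = ev,
      oscillatory = abs(Im(ev[1])) > 1e-12)
  }
  roots
}

# Leading eigenvalue real part of the fixed point continued from x_prev.
mf_lead_re <- function(params, het, eta, x_prev) {
  het$eta_bar <- eta
  x <- mf_newton(x_prev, params, het)
  if (is.null(x)) return(list(re = NA_real_, x = NULL))
  ev <- eigen(mf_jacobian(x, params, het), only.values = TRUE)$values
  list(re = max(Re(ev)), x = x,
       im = abs(Im(ev[which.max(Re(ev))])))
}

#' Scan the bifurcation structure in the mean drive
#'
#' Continues the fixed point of the mean-field reduction along an
#' increasing grid of \code{eta_bar} (predictor-free continuation: Newton
#' from the previous solution), records stability, locates Hopf points by
#' bisection on the leading eigenvalue real part, and measures stable
#' limit-cycle extrema of the rate by long integration inside the unstable
#' window.
#'
#' @inheritParams meanfield_rhs
#' @param eta_grid strictly increasing grid of mean drives (pA).
#' @param cycle_tmax integration horizon used to measure limit-cycle
#'   extrema (ms).
#' @param n_cycle_probe number of grid points inside the oscillatory window
#'   at which cycle extrema are measured (all if fewer).
#' @return An object of class \code{"snn_bifurcation"}: list with
#'   \code{branch} (data.frame \code{eta_bar}, \code{r_fixed},
#'   \code{v_bar}, \code{stable}, \code{lead_re}, \code{r_cycle_min},
#'   \code{r_cycle_max}), \code{hopf} (numeric vector of Hopf locations in
#'   pA), \code{params} and \code{het} echoes.
#' @export
scan_bifurcation <- function(params, het, eta_grid,
                             cycle_tmax = 4000, n_cycle_probe = 7) {
  if (is.unsorted(eta_grid, strictly = TRUE))
    stop("scan_bifurcation: eta_grid must be strictly increasing", call. = FALSE)
  m <- length(eta_grid)
  r_fix <- v_fix <- lead <- rep(NA_real_, m)
  stab <- rep(NA, m)
  states <- vector("list", m)
  x <- c(1e-5, params$v_r, 0, 1e-4)
  for (i in seq_len(m)) {
    het_i <- het; het_i$eta_bar <- eta_grid[i]
    xi <- mf_newton(x, params, het_i)
    if (is.null(xi)) {
      fps <- find_fixed_points(params, het, eta_bar = eta_grid[i])
      if (length(fps) == 0) next
      xi <- fps[[1]]$state
    }
    x <- xi; states[[i]] <- xi
    ev <- eigen(mf_jacobian(xi, params, het_i), only.values = TRUE)$values
    r_fix[i] <- xi[1]; v_fix[i] <- xi[2]
    lead[i] <- max(Re(ev)); stab[i] <- lead[i] < 0
  }
  # Hopf bisection on sign changes of the leading eigenvalue real part
  hopf <- numeric(0)
  for (i in seq_len(m - 1)) {
    if (is.na(lead[i]) || is.na(lead[i + 1])) next
    if (sign(lead[i]) == sign(lead[i + 1])) next
    lo <- eta_grid[i]; hi <- eta_grid[i + 1]
    flo <- lead[i]; xcur <- states[[i]]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      res <- mf_lead_re(params, het, mid, xcur)
      if (is.na(res$re)) break
      xcur <- res$x
      if (sign(res$re) == sign(flo)) { lo <- mid; flo <- res$re } else hi <- mid
      if (hi - lo < 1e-4 * (eta_grid[i + 1] - eta_grid[i])) break
    }
    hopf <- c(hopf, (lo + hi) / 2)
  }
  # limit-cycle extrema inside unstable windows
  cyc_min <- cyc_max <- rep(NA_real_, m)
  unst <- which(!is.na(stab) & !stab)
  if (length(unst) > 0) {
    probe <- unst[unique(round(seq(1, length(unst),
                                   length.out = min(n_cycle_probe,
                                                    length(unst)))))]
    for (i in probe) {
      het_i <- het; het_i$eta_bar <- eta_grid[i]
      x0 <- states[[i]]
      x0 <- x0 + c(max(1e-4, 0.1 * x0[1]), 1, 0, 0)
      traj <- tryCatch(
        integrate_meanfield(x0, params, het_i, duration = cycle_tmax, dt = 1),
        error = function(e) NULL)
      if (is.null(traj)) next
      tail_r <- traj$r[traj$time > cycle_tmax / 2]
      cyc_min[i] <- min(tail_r); cyc_max[i] <- max(tail_r)
    }
  }
  out <- list(branch = data.frame(eta_bar = eta_grid, r_fixed = r_fix,
                                  v_bar = v_fix, stable = stab,
                                  lead_re = lead,
                                  r_cycle_min = cyc_min,
                                  r_cycle_max = cyc_max),
              hopf = hopf, params = params, het = het)
  class(out) <- "snn_bifurcation"
  out
}

#' @export
print.snn_bifurcation <- function(x, ...) {
  b <- x$branch
  cat(sprintf("snn_bifurcation: %d grid points, eta_bar in [%g, %g] pA\n",
              nrow(b), min(b$eta_bar), max(b$eta_bar)))
  if (length(x$hopf))
    cat("  Hopf points at eta_bar =",
        paste(sprintf("%.2f", x$hopf), collapse = ", "), "pA\n")
  else cat("  no Hopf points detected on the grid\n")
  cat(sprintf("  fixed-point rate range: [%.4g, %.4g] kHz\n",
              min(b$r_fixed, na.rm = TRUE), max(b$r_fixed, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.snn_bifurcation <- function(x, ...) {
  b <- x$branch
  graphics::plot(b$eta_bar, b$r_fixed, type = "n",
                 xlab = "mean drive (pA)", ylab = "rate r (kHz)", ...)
  st <- b$stable %in% TRUE
  graphics::lines(b$eta_bar[st], b$r_fixed[st], col = "darkgreen", lwd = 2)
  graphics::lines(b$eta_bar[!st], b$r_fixed[!st], col = "blue", lty = 2)
  ok <- !is.na(b$r_cycle_min)
  graphics::points(b$eta_bar[ok], b$r_cycle_min[ok], col = "red", pch = 1)
  graphics::points(b$eta_bar[ok], b$r_cycle_max[ok], col = "red", pch = 1)
  graphics::abline(v = x$hopf, col = "grey", lty = 3)
  invisible(x)
}

#' Export a bifurcation scan
#'
#' Writes the branch as CSV (columns \code{eta_bar}, \code{r_fixed},
#' \code{stability}, \code{r_cycle_min}, \code{r_cycle_max}) and the
#' special points as a side JSON file.
#'
#' @param x an \code{"snn_bifurcation"} object.
#' @param path CSV output path; the JSON is written next to it with
#'   extension \code{.json}.
#' @return The CSV path, invisibly.
#' @export
write_bifurcation <- function(x, path) {
  stopifnot(inherits(x, "snn_bifurcation"))
  b <- x$branch
  utils::write.csv(
    data.frame(eta_bar = b$eta_bar, r_fixed = b$r_fixed,
               stability = ifelse(b$stable, "stable", "unstable"),
               r_cycle_min = b$r_cycle_min, r_cycle_max = b$r_cycle_max),
    path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(hopf_eta_bar = x$hopf),
                       sub("\\.csv$", ".json", path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Classify the dynamical regime at a given mean drive
#'
#' Labels the regime of the mean-field reduction at \code{eta_bar}:
#' \code{"quiescent"} if the only stable attractor is a fixed point with
#' rate below \code{rate_floor}; \code{"persistent"} if a stable fixed
#' point has rate above the floor; \code{"oscillatory"} if the fixed point
#' is unstable and integration settles onto a limit cycle. Ambiguous or
#' bistable configurations are flagged rather than silently resolved.
#'
#' @inheritParams meanfield_rhs
#' @param eta_bar mean external drive (pA).
#' @param rate_floor rate threshold separating quiescence from persistent
#'   activity (kHz per neuron).
#' @param cycle_tmax integration horizon used to confirm a limit cycle (ms).
#' @return List with \code{label} in \code{c("quiescent", "oscillatory",
#'   "persistent")}, logical \code{ambiguous}, and supporting detail.
#' @export
classify_regime <- function(params, het, eta_bar, rate_floor = 0.001,
                            cycle_tmax = 3000) {
  fps <- find_fixed_points(params, het, eta_bar = eta_bar)
  het$eta_bar <- eta_bar
  stable <- Filter(function(f) f$stable, fps)
  unstable <- Filter(function(f) !f$stable, fps)
  cycle <- NULL
  if (length(unstable) > 0) {
    x0 <- unstable[[1]]$state + c(max(1e-4, 0.1 * unstable[[1]]$state[1]),
                                  1, 0, 0)
    traj <- tryCatch(
      integrate_meanfield(x0, params, het, duration = cycle_tmax, dt = 1),
      error = function(e) NULL)
    if (!is.null(traj)) {
      tail_r <- traj$r[traj$time > cycle_tmax / 2]
      if (max(tail_r) - min(tail_r) > max(1e-4, 0.05 * mean(tail_r)))
        cycle <- c(min(tail_r), max(tail_r))
    }
  }
  has_cycle <- !is.null(cycle)
  has_persist <- any(vapply(stable, function(f) f$state[1] >= rate_floor,
                            logical(1)))
  has_quiet <- any(vapply(stable, function(f) f$state[1] < rate_floor,
                          logical(1)))
  label <- if (has_cycle) "oscillatory"
  else if (has_persist) "persistent"
  else "quiescent"
  ambiguous <- (has_cycle && (has_persist || has_quiet)) ||
    (has_persist && has_quiet) || (length(fps) == 0)
  list(label = label, ambiguous = ambiguous,
       fixed_points = fps, cycle_r_range = cycle)
}
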