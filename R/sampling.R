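#' Draw from a (optionally truncated) Lorentzian distribution
#'
#' Samples i.i.d. values from the Cauchy/Lorentzian density with the given
#' center and half-width-at-half-maximum. When \code{bounds} are supplied
#' the density is restricted to the interval by rejection, which preserves
#' the Lorentzian shape on the support. A zero half-width is the degenerate
#' point mass at the center.
#'
#' @param n number of draws.
#' @param center distribution center (location).
#' @param half_width half-width-at-half-maximum (scale), \code{>= 0}.
#' @param bounds optional length-2 support interval containing the center.
#' @param seed optional integer seed; when supplied the draw is a pure
#'   function of \code{(n, center, half_width, bounds, seed)}.
#' @param max_tries rejection is abandoned (with an error) if the observed
#'   acceptance rate falls below \code{1e-3} after this many proposal rounds.
#'
#' @return Numeric vector of length \code{n}.
#' @examples
#' x <- sample_lorentzian(1000, center = 0, half_width = 1, seed = 1)
#' th <- sample_lorentzian(1000, 0.5, 0.05, bounds = c(0, 1), seed = 1)
#' @export
sample_lorentzian <- function(n, center, half_width, bounds = NULL,
                              seed = NULL, max_tries = 50L) {
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width < 0)
    stop("sample_lorentzian: half_width must be a scalar >= 0", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("sample_lorentzian: n must be a nonnegative count", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(bounds)) {
    if (length(bounds) != 2L || bounds[1] >= bounds[2])
      stop("sample_lorentzian: bounds must be an increasing interval",
           call. = FALSE)
    # the closed support must contain the center (a center sitting on the
    # boundary keeps a valid rejection sampler: half the mass is proposed
    # inside)
    if (center < bounds[1] || center > bounds[2])
      stop("sample_lorentzian: bounds exclude the center", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  if (half_width == 0) return(rep(center, n))
  if (is.null(bounds)) return(stats::rcauchy(n, location = center,
                                             scale = half_width))
  out <- numeric(0)
  proposed <- 0
  tries <- 0L
  while (length(out) < n) {
    m <- max(n - length(out), 1000L)
    x <- stats::rcauchy(m, location = center, scale = half_width)
    keep <- x >= bounds[1] & x <= bounds[2]
    out <- c(out, x[keep])
    proposed <- proposed + m
    tries <- tries + 1L
    if (tries >= max_tries && length(out) / proposed < 1e-3)
      stop("sample_lorentzian: rejection acceptance rate below 1e-3 ",
           "(degenerate bounds)", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Quantile function of the truncated Lorentzian
#'
#' Closed-form inverse-CDF of the Lorentzian restricted to a support
#' interval. Used as an independent check on the rejection sampler and to
#' compute exact quartiles.
#'
#' @param p probabilities in \code{[0, 1]}.
#' @inheritParams sample_lorentzian
#' @return Numeric vector of quantiles.
#' @export
qlorentzian <- function(p, center, half_width, bounds = NULL) {
  if (half_width == 0) return(rep(center, length(p)))
  if (is.null(bounds))
    return(stats::qcauchy(p, location = center, scale = half_width))
  Fa <- stats::pcauchy(bounds[1], center, half_width)
  Fb <- stats::pcauchy(bounds[2], center, half_width)
  stats::qcauchy(Fa + p * (Fb - Fa), center, half_width)
}
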