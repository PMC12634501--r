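#' Square drive pulse
#'
#' A brief global stimulation pulse: constant \code{amplitude} on
#' \code{[onset, onset + width)}, zero elsewhere. Pulses compose additively
#' when passed as a list to [simulate_network()].
#'
#' @param amplitude pulse amplitude (pA).
#' @param onset pulse onset (ms).
#' @param width pulse width (ms), \code{> 0}.
#' @return An object of class \code{"drive_pulse"}.
#' @export
make_pulse <- function(amplitude, onset = 0, width = 50) {
  if (!is.numeric(width) || width <= 0)
    stop("make_pulse: width must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, onset = onset, width = width),
            class = "drive_pulse")
}

#' Periodic train of brief pulses
#'
#' A sequence of identical square pulses, one per period, covering
#' \code{[onset, onset + duration)}. Used as the entraining stimulus of the
#' reservoir experiments: a train at the target's fundamental frequency
#' phase-locks the oscillatory network so the decoded output remains valid
#' beyond the training interval.
#'
#' @inheritParams make_pulse
#' @param period pulse period (ms), \code{> width}.
#' @param duration total span covered by the train (ms).
#' @return List of \code{"drive_pulse"} objects (additive composition).
#' @export
make_pulse_train <- function(amplitude, width = 60, period = 1000 / 6,
                             duration, onset = 0) {
  if (period <= width)
    stop("make_pulse_train: period must exceed width", call. = FALSE)
  onsets <- seq(onset, onset + duration, by = period)
  lapply(onsets, function(o) make_pulse(amplitude, o, width))
}

#' Dominant frequency of a sampled signal
#'
#' Frequency of the periodogram peak (taper 10%), in Hz, of a regularly
#' sampled series. Used to measure collective oscillation frequencies of
#' network and mean-field trajectories.
#'
#' @param x numeric series.
#' @param dt sampling interval (ms).
#' @return Dominant frequency (Hz).
#' @export
dominant_frequency <- function(x, dt) {
  x <- x - mean(x)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1 / dt), plot = FALSE,
                          taper = 0.1)
  sp$freq[which.max(sp$spec)] * 1000
}

new_event_dataset <- function(events, labels, n_classes, n_channels,
                              duration, config) {
  d <- list(events = events, labels = labels, n_classes = n_classes,
            n_channels = n_channels, duration = duration, config = config)
  class(d) <- "event_dataset"
  d
}

#' @export
print.event_dataset <- function(x, ...) {
  cat(sprintf("event_dataset: %d samples, %d classes, %d channels, %g ms\n",
              length(x$events), x$n_classes, x$n_channels, x$duration))
  cat(sprintf("  mean events per sample: %.1f\n",
              mean(vapply(x$events, nrow, numeric(1)))))
  invisible(x)
}

#' Rate-coded event-stream classification task
#'
#' Synthetic Poisson event streams where class \code{k} elevates the firing
#' rate of a disjoint subset of channels by \code{contrast}; the classes
#' are separable from spike counts alone. Classes are balanced.
#'
#' @param n_classes number of classes (\code{>= 2}).
#' @param n_channels number of input channels; must admit disjoint subsets
#'   (\code{n_channels >= 2 * n_classes}).
#' @param n_samples total number of samples.
#' @param duration sample duration (ms).
#' @param base_rate background Poisson rate per channel (Hz).
#' @param contrast additive rate elevation of the class channels (Hz).
#' @param seed integer seed; the dataset is a pure function of the
#'   arguments.
#' @return An object of class \code{"event_dataset"}: per-sample event
#'   data.frames (\code{time_ms}, \code{channel}), integer \code{labels}
#'   in \code{0 .. n_classes - 1}, and a config echo.
#' @export
make_rate_task <- function(n_classes = 2, n_channels = 64, n_samples = 200,
                           duration = 100, base_rate = 20, contrast = 80,
                           seed = 1L) {
  if (n_classes < 2) stop("make_rate_task: need >= 2 classes", call. = FALSE)
  if (n_channels < 2 * n_classes)
    stop("make_rate_task: need n_channels >= 2 * n_classes", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  per <- n_channels %/% n_classes
  subset_of <- function(k) (k * per + 1):(k * per + per)  # disjoint
  labels <- rep(seq_len(n_classes) - 1L, length.out = n_samples)
  events <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    rates <- rep(base_rate, n_channels)
    rates[subset_of(labels[i])] <- base_rate + contrast
    counts <- stats::rpois(n_channels, rates * duration / 1000)
    ch <- rep(seq_len(n_channels), counts)
    tm <- stats::runif(sum(counts), 0, duration)
    o <- order(tm)
    events[[i]] <- data.frame(time_ms = tm[o], channel = ch[o])
  }
  new_event_dataset(events, labels, n_classes, n_channels, duration,
                    list(task = "rate", base_rate = base_rate,
                         contrast = contrast, seed = seed))
}

#' Timing-coded event-stream classification task
#'
#' Classes share identical channel-marginal spike counts (exactly
#' \code{spikes_per_channel} events on every channel in every sample) but
#' differ in class-specific spike-timing templates perturbed by Gaussian
#' jitter truncated to the sample window. Count-based classifiers are at
#' chance by construction; timing-aware classifiers are not.
#'
#' @inheritParams make_rate_task
#' @param spikes_per_channel events per channel per sample.
#' @param jitter_sd standard deviation of the timing jitter (ms).
#' @return An \code{"event_dataset"} (see [make_rate_task()]).
#' @export
make_temporal_task <- function(n_classes = 2, n_channels = 64,
                               n_samples = 200, duration = 100,
                               spikes_per_channel = 1, jitter_sd = 3,
                               seed = 1L) {
  if (n_classes < 2) stop("make_temporal_task: need >= 2 classes", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  # class templates: fixed spike times per channel, same count everywhere
  templates <- lapply(seq_len(n_classes), function(k)
    matrix(stats::runif(n_channels * spikes_per_channel, 0, duration),
           nrow = n_channels))
  labels <- rep(seq_len(n_classes) - 1L, length.out = n_samples)
  events <- vector("list", n_samples)
  eps <- sqrt(.Machine$double.eps)
  for (i in seq_len(n_samples)) {
    tpl <- templates[[labels[i] + 1L]]
    tm <- as.vector(tpl) + stats::rnorm(length(tpl), 0, jitter_sd)
    tm <- pmin(pmax(tm, 0), duration - eps)  # truncate to the window
    ch <- rep(seq_len(n_channels), times = spikes_per_channel)
    o <- order(tm)
    events[[i]] <- data.frame(time_ms = tm[o], channel = ch[o])
  }
  new_event_dataset(events, labels, n_classes, n_channels, duration,
                    list(task = "temporal",
                         spikes_per_channel = spikes_per_channel,
                         jitter_sd = jitter_sd, seed = seed))
}

#' Write / read an event dataset as plain CSV
#'
#' Events are stored as one CSV (\code{sample_id}, \code{time_ms},
#' \code{channel}) and labels as a second CSV (\code{sample_id},
#' \code{label}).
#'
#' @param dataset an \code{"event_dataset"}.
#' @param events_path,labels_path output file paths.
#' @return \code{write_events}: \code{events_path}, invisibly;
#'   \code{read_events}: an \code{"event_dataset"} (config echo not
#'   preserved).
#' @export
write_events <- function(dataset, events_path, labels_path) {
  stopifnot(inherits(dataset, "event_dataset"))
  ev <- do.call(rbind, lapply(seq_along(dataset$events), function(i) {
    e <- dataset$events[[i]]
    if (nrow(e) == 0) return(NULL)
    data.frame(sample_id = i, time_ms = e$time_ms, channel = e$channel)
  }))
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = seq_along(dataset$labels),
                              label = dataset$labels),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(events_path)
}

#' @rdname write_events
#' @param n_channels,duration dataset geometry (not inferable from the
#'   files when channels or late times never occur).
#' @export
read_events <- function(events_path, labels_path, n_channels = NULL,
                        duration = NULL) {
  ev <- utils::read.csv(events_path)
  lb <- utils::read.csv(labels_path)
  lb <- lb[order(lb$sample_id), ]
  n <- nrow(lb)
  events <- vector("list", n)
  sp <- split(ev, factor(ev$sample_id, levels = lb$sample_id))
  for (i in seq_len(n)) {
    e <- sp[[i]]
    events[[i]] <- if (is.null(e) || nrow(e) == 0)
      data.frame(time_ms = numeric(0), channel = integer(0))
    else data.frame(time_ms = e$time_ms, channel = e$channel)
  }
  if (is.null(n_channels)) n_channels <- max(ev$channel)
  if (is.null(duration)) duration <- max(ev$time_ms) + 1
  new_event_dataset(events, lb$label, length(unique(lb$label)),
                    n_channels, duration, list(task = "from_file"))
}
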