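#' Acquisition configuration for the spike-rate signal chain
#'
#' Bundles every parameter of the front-end signal chain: band-pass filtering
#' of the raw extracellular voltage, threshold-crossing spike detection at a
#' multiple of the channel RMS, binned spike counting, and the trailing-window
#' spike rate metric (SRM).
#'
#' @param sampling_rate Samples per second of the raw traces (default 30000).
#' @param band_low,band_high Band-pass edges in Hz (defaults 250 and 7500).
#' @param threshold_mult Detection threshold as a multiple of the filtered
#'   trace RMS (default 4.5).
#' @param polarity Crossing polarity: `"negative"` (extracellular convention,
#'   default), `"positive"`, or `"both"`.
#' @param lockout Dead time in seconds after a detected event during which
#'   further crossings are suppressed (default 0.001).
#' @param bin_width Spike-count bin width in seconds (default 0.050).
#' @param srm_window Trailing window in seconds over which binned counts are
#'   averaged to form the SRM (default 1.0). Must be an integer multiple of
#'   `bin_width`.
#'
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' cfg <- acq_config()
#' cfg$srm_window / cfg$bin_width  # 20 bins per SRM window
acq_config <- function(sampling_rate = 30000, band_low = 250, band_high = 7500,
                       threshold_mult = 4.5,
                       polarity = c("negative", "positive", "both"),
                       lockout = 0.001, bin_width = 0.05, srm_window = 1.0) {
  polarity <- match.arg(polarity)
  if (sampling_rate <= 2 * band_high)
    stop("sampling_rate must exceed twice band_high (Nyquist)")
  if (band_low <= 0 || band_low >= band_high)
    stop("require 0 < band_low < band_high")
  if (threshold_mult <= 0) stop("threshold_mult must be positive")
  if (bin_width <= 0 || bin_width > srm_window)
    stop("require 0 < bin_width <= srm_window")
  n_bins <- srm_window / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("srm_window must be an integer multiple of bin_width")
  if (lockout < 0) stop("lockout must be non-negative")
  structure(list(sampling_rate = sampling_rate, band_low = band_low,
                 band_high = band_high, threshold_mult = threshold_mult,
                 polarity = polarity, lockout = lockout,
                 bin_width = bin_width, srm_window = srm_window),
            class = "acq_config")
}

#' Raw voltage trace for one channel
#'
#' @param samples Numeric vector of voltages (microvolts).
#' @param channel_id Integer channel identifier.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, channel_id = 1L, t0 = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (length(channel_id) != 1L || channel_id < 1)
    stop("channel_id must be a single positive integer")
  structure(list(channel_id = as.integer(channel_id), samples = samples,
                 t0 = t0), class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> channel %d, %d samples, t0 = %g s\n",
              x$channel_id, length(x$samples), x$t0))
  invisible(x)
}

#' Zero-phase band-pass filter a raw trace
#'
#' Applies a 4th-order zero-phase Butterworth band-pass (a 2nd-order design
#' run forward and backward), removing DC and out-of-band components with
#' unit pass-band gain and no group delay.
#'
#' @param trace A [raw_trace()].
#' @param cfg An [acq_config()]; `band_low`/`band_high` set the pass band.
#' @return A filtered `raw_trace` of the same length.
#' @export
bandpass_filter <- function(trace, cfg = acq_config()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(cfg, "acq_config"))
  nyq <- cfg$sampling_rate / 2
  if (cfg$band_low <= 0 || cfg$band_high >= nyq)
    stop("band edges must lie strictly inside (0, Nyquist)")
  if (length(trace$samples) < 3 * cfg$sampling_rate / cfg$band_low)
    warning("trace shorter than ~3 filter time constants; edge transients dominate")
  bf <- signal::butter(2, c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  out <- signal::filtfilt(bf, trace$samples)
  res <- raw_trace(out, trace$channel_id, trace$t0)
  attr(res, "filtered") <- TRUE
  res
}

#' Detected spike events for one channel
#'
#' @param channel_id Integer channel identifier.
#' @param times Strictly increasing event times in seconds.
#' @param threshold Threshold (volts in trace units) used for detection, if any.
#' @param polarity Crossing polarity used.
#' @return An object of class `spike_events`.
#' @export
spike_events <- function(channel_id, times, threshold = NA_real_,
                         polarity = "negative") {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("event times must be strictly increasing")
  structure(list(channel_id = as.integer(channel_id), times = times,
                 threshold = threshold, polarity = polarity),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> channel %d: %d events", x$channel_id,
              length(x$times)))
  if (!is.na(x$threshold))
    cat(sprintf(" (threshold %.3g, %s)", x$threshold, x$polarity))
  cat("\n")
  invisible(x)
}

#' Detect threshold-crossing spike events
#'
#' Unsorted single/multi-unit action potentials are extracted by marking every
#' crossing of `threshold_mult` times the RMS of the (already filtered) trace.
#' With negative polarity an event is the sample at which the trace first drops
#' below -threshold; crossings within `lockout` of the previous event are
#' suppressed so one waveform is counted once.
#'
#' @param trace A filtered [raw_trace()].
#' @param cfg An [acq_config()].
#' @param threshold Optional manual threshold override (positive, in trace
#'   units), mirroring experimenter adjustment after visual inspection; when
#'   `NULL` (default) it is `threshold_mult * rms(trace)`.
#' @return A [spike_events()] object carrying the threshold actually used.
#' @export
detect_threshold_crossings <- function(trace, cfg = acq_config(),
                                       threshold = NULL) {
  stopifnot(inherits(trace, "raw_trace"), inherits(cfg, "acq_config"))
  x <- trace$samples
  if (is.null(threshold)) {
    rms <- sqrt(mean(x^2))
    if (rms == 0) stop("flat trace: RMS is zero, cannot set threshold")
    threshold <- cfg$threshold_mult * rms
  }
  if (threshold <= 0) stop("threshold must be positive")
  n <- length(x)
  idx <- integer(0)
  if (cfg$polarity %in% c("negative", "both")) {
    neg <- which(x[-1] < -threshold & x[-n] >= -threshold) + 1L
    if (x[1] < -threshold) neg <- c(1L, neg)
    idx <- c(idx, neg)
  }
  if (cfg$polarity %in% c("positive", "both")) {
    pos <- which(x[-1] > threshold & x[-n] <= threshold) + 1L
    if (x[1] > threshold) pos <- c(1L, pos)
    idx <- c(idx, pos)
  }
  idx <- sort(unique(idx))
  lock_samp <- cfg$lockout * cfg$sampling_rate
  if (length(idx) > 1 && lock_samp > 0) {
    keep <- idx[1]
    last <- idx[1]
    for (i in idx[-1]) {
      if (i - last >= lock_samp) {
        keep <- c(keep, i)
        last <- i
      }
    }
    idx <- keep
  }
  spike_events(trace$channel_id, trace$t0 + (idx - 1L) / cfg$sampling_rate,
               threshold = threshold, polarity = cfg$polarity)
}

#' Binned spike counts for one channel
#'
#' @param channel_id Integer channel identifier.
#' @param counts Non-negative integer counts per bin.
#' @param bin_width Bin width in seconds.
#' @param t0 Start time of the first bin (seconds).
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(channel_id, counts, bin_width, t0 = 0) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(channel_id = as.integer(channel_id), counts = counts,
                 bin_width = bin_width, t0 = t0), class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> channel %d: %d bins of %g s from t0 = %g s, total %d events\n",
              x$channel_id, length(x$counts), x$bin_width, x$t0,
              sum(x$counts)))
  invisible(x)
}

#' Bin spike events into contiguous half-open count bins
#'
#' Bins are anchored at the start of `span` and are half-open
#' `[t, t + bin_width)`, so re-binning the same events is deterministic and the
#' total count over the span is conserved.
#'
#' @param events A [spike_events()] object.
#' @param cfg An [acq_config()] providing `bin_width`.
#' @param span Numeric `c(t_start, t_end)` in seconds.
#' @return A [binned_counts()] object.
#' @export
bin_spike_counts <- function(events, cfg = acq_config(), span) {
  stopifnot(inherits(events, "spike_events"), inherits(cfg, "acq_config"))
  t0 <- span[1]; t1 <- span[2]
  if (t1 <= t0) stop("span end must exceed span start")
  bw <- cfg$bin_width
  n_bins <- ceiling((t1 - t0) / bw - 1e-9)
  tt <- events$times
  tt <- tt[tt >= t0 & tt < t0 + n_bins * bw]
  bin_idx <- floor((tt - t0) / bw) + 1L
  bin_idx[bin_idx > n_bins] <- n_bins  # guard against FP roundoff at the edge
  binned_counts(events$channel_id, tabulate(bin_idx, nbins = n_bins), bw, t0)
}

#' Spike rate metric at a time point
#'
#' The SRM is the arithmetic mean of the binned counts over the trailing
#' `srm_window` (by default the 20 most recent complete 50 ms bins, i.e. the
#' past one second). Before a full window has accrued the mean over the
#' available bins is returned and flagged as warm-up.
#'
#' @param counts A [binned_counts()] object.
#' @param t Query time in seconds; bins ending at or before `t` contribute.
#' @param cfg An [acq_config()] providing `srm_window`.
#' @return An object of class `rate_sample` with fields `t`, `channel_id`,
#'   `srm` (mean spikes per bin) and `warm_up`.
#' @export
spike_rate_metric <- function(counts, t, cfg = acq_config()) {
  stopifnot(inherits(counts, "binned_counts"), inherits(cfg, "acq_config"))
  bw <- counts$bin_width
  n_win <- round(cfg$srm_window / bw)
  k <- floor((t - counts$t0) / bw + 1e-9)
  if (k < 1) stop("no complete bins at or before t")
  k <- min(k, length(counts$counts))
  use <- counts$counts[max(1L, k - n_win + 1L):k]
  structure(list(t = t, channel_id = counts$channel_id, srm = mean(use),
                 warm_up = k < n_win), class = "rate_sample")
}

# SRM at the end of every bin, as a vector: trailing mean over the last
# n = srm_window/bin_width bins, partial means during warm-up.
srm_series <- function(counts, cfg = acq_config()) {
  n <- round(cfg$srm_window / counts$bin_width)
  cs <- cumsum(counts$counts)
  i <- seq_along(cs)
  lag <- pmax(i - n, 0L)
  (cs - c(0, cs)[lag + 1L]) / pmin(i, n)
}

#' Read/write spike events and binned counts as CSV
#'
#' Plain-text interchange: spike events as `channel_id,time_s`; binned counts
#' as `t_bin_start_s,channel_id,count`.
#'
#' @param x A [spike_events()] or [binned_counts()] object.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_spike_events` returns a
#'   [spike_events()].
#' @export
write_spike_events <- function(x, path) {
  stopifnot(inherits(x, "spike_events"))
  df <- data.frame(channel_id = x$channel_id, time_s = x$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  df <- utils::read.csv(path)
  spike_events(df$channel_id[1] %||% 1L, df$time_s)
}

#' @rdname write_spike_events
#' @export
write_binned_counts <- function(x, path) {
  stopifnot(inherits(x, "binned_counts"))
  df <- data.frame(
    t_bin_start_s = x$t0 + (seq_along(x$counts) - 1L) * x$bin_width,
    channel_id = x$channel_id, count = x$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
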