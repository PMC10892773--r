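#' Bandpass-filter a recording
#'
#' Causal 4th-order Butterworth bandpass (default 0.3-20 Hz) applied per
#' channel, removing the gravity/DC component and out-of-band noise while
#' keeping all clinical tremor bands (2-12 Hz).  Output length equals input
#' length; the filter warm-up transient is left in place (downstream window
#' statistics are robust to it and phase is not used).
#'
#' @param recording a `pd_recording`.
#' @param low,high passband edges in Hz.
#' @param order Butterworth prototype order.
#' @return filtered `pd_recording`.
#' @export
bandpass_filter <- function(recording, low = 0.3, high = 20, order = 4L) {
  fs <- recording$sample_rate
  if (high >= fs / 2)
    pd_stop(sprintf("high edge %g Hz >= Nyquist %g Hz", high, fs / 2),
            "pdmil_error_filter_design")
  if (!all(is.finite(recording$data)))
    pd_stop("recording contains non-finite samples", "pdmil_error_nonfinite")
  if (nrow(recording$data) <= 3 * order)
    pd_stop("recording too short for filter warm-up", "pdmil_error_duration")
  filt <- butter_bandpass(low, high, fs, order)
  out <- recording
  for (ch in seq_len(ncol(recording$data)))
    out$data[, ch] <- apply_sos(filt, recording$data[, ch])
  out
}

#' Z-score normalize a recording
#'
#' Per channel, per recording: subtract the mean and divide by the
#' population standard deviation, so every channel has mean 0 and sd 1.
#' A zero-variance channel is mapped to all zeros with a warning rather
#' than failing (degenerate synthetic inputs are legal).
#'
#' @param recording a `pd_recording`.
#' @return normalized `pd_recording`.
#' @export
zscore_normalize <- function(recording) {
  out <- recording
  n <- nrow(recording$data)
  for (ch in seq_len(ncol(recording$data))) {
    x <- recording$data[, ch]
    mu <- mean(x)
    sdev <- sqrt(sum((x - mu)^2) / n)
    if (sdev == 0) {
      pd_warn(sprintf("channel %d has zero variance; normalized to zeros", ch),
              "pdmil_warning_zero_variance")
      out$data[, ch] <- 0
    } else {
      out$data[, ch] <- (x - mu) / sdev
    }
  }
  out
}

# valid window start indices (0-based) for N samples, width W, step S
window_starts <- function(n, window = 300L, step = 150L) {
  if (n < window) return(integer(0))
  seq.int(0L, n - window, by = step)
}

#' Slice a recording into fixed overlapping windows
#'
#' Windows of `window` samples (default 300 = 1.5 s at 200 Hz) with the
#' given overlap (default 50%, step 150).  Trailing samples that do not
#' fill a whole window are discarded.  These windows are the
#' multiple-instance-learning "instances".
#'
#' @param recording a `pd_recording` (normally filtered and normalized).
#' @param window window length in samples.
#' @param overlap fractional overlap in [0, 1).
#' @return list of `pd_window` segments, chronological; each has `samples`
#'   (window x 6 matrix), 0-based `window_index` and `start_sample`.
#' @export
segment_windows <- function(recording, window = 300L, overlap = 0.5) {
  n <- nrow(recording$data)
  if (n < window)
    pd_stop(sprintf("recording has %d samples; at least %d required", n, window),
            "pdmil_error_too_short")
  step <- as.integer(round(window * (1 - overlap)))
  starts <- window_starts(n, window, step)
  lapply(seq_along(starts), function(i)
    structure(list(subject_id = recording$subject_id,
                   activity_id = recording$activity_id,
                   window_index = i - 1L,
                   start_sample = starts[i],
                   samples = recording$data[(starts[i] + 1L):(starts[i] + window), ,
                                            drop = FALSE]),
              class = "pd_window"))
}

#' Run the full preprocessing chain on one recording
#'
#' Order is fixed: bandpass filter, then z-score normalization, then
#' window segmentation.
#'
#' @param recording a `pd_recording`.
#' @param config optional list overriding `filter.low_hz`, `filter.high_hz`,
#'   `filter.order`, `window.samples`, `window.overlap`.
#' @return list of `pd_window` segments.
#' @export
preprocess_recording <- function(recording, config = NULL) {
  cfg <- merge_config(list(
    filter = list(low_hz = 0.3, high_hz = 20, order = 4L),
    window = list(samples = 300L, overlap = 0.5)), config)
  rec <- bandpass_filter(recording, cfg$filter$low_hz, cfg$filter$high_hz,
                         cfg$filter$order)
  rec <- zscore_normalize(rec)
  segment_windows(rec, cfg$window$samples, cfg$window$overlap)
}
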