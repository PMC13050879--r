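#' Band-pass filter every trial and channel
#'
#' Zero-phase Butterworth filtering of the task-relevant band (default
#' 0.5-30 Hz, covering the mu and beta sensorimotor rhythms). The filter is
#' applied forward-backward (`signal::filtfilt`) so waveform latencies are
#' preserved, on a reflect-padded copy of each trace to suppress edge
#' transients on the short epoched windows.
#'
#' @param x an `eeg_epochs` object.
#' @param band_low,band_high passband edges in Hz; `0 <= band_low <
#'   band_high < fs/2` is required.
#' @param order Butterworth order of each directional pass (default 4).
#' @return the filtered `eeg_epochs` (same shape).
#' @export
bandpass_epochs <- function(x, band_low = 0.5, band_high = 30, order = 4) {
  validate_epochs(x)
  nyq <- x$fs / 2
  if (!(band_low >= 0 && band_low < band_high))
    stop("need 0 <= band_low < band_high", call. = FALSE)
  if (band_high >= nyq)
    stop(sprintf("band_high (%g Hz) must be below Nyquist (%g Hz)",
                 band_high, nyq), call. = FALSE)
  # wide EEG bands (e.g. 0.5-30 Hz at fs 250) make a single band-pass
  # design ill-conditioned, so low-pass and high-pass are cascaded
  lp <- signal::butter(order, band_high / nyq, type = "low")
  hp <- if (band_low > 0)
    signal::butter(order, band_low / nyq, type = "high") else NULL
  T <- n_samples(x)
  # padding must absorb the high-pass transient (~fs/band_low samples)
  pad <- if (band_low > 0) min(T - 1L, as.integer(ceiling(3 * x$fs / band_low)))
         else min(T - 1L, 300L)
  out <- x$data
  for (i in seq_len(n_trials(x))) {
    for (c in seq_len(n_channels(x))) {
      v <- x$data[i, c, ]
      # even (mirror) reflection: continuous at the edge, no DC offset
      left  <- v[(pad + 1L):2L]
      right <- v[(T - 1L):(T - pad)]
      f <- signal::filtfilt(lp, c(left, v, right))
      if (!is.null(hp)) f <- signal::filtfilt(hp, f)
      out[i, c, ] <- f[(pad + 1L):(pad + T)]
    }
  }
  y <- x
  y$data <- out
  y
}

#' Crop each trial to a time window
#'
#' Retains the half-open window `[crop_start, crop_end)` (seconds, on the
#' same clock as `t_start`), e.g. keeping the 2-6 s imagery segment of an
#' 8 s trial at 250 Hz yields 1000 samples.
#'
#' @param x an `eeg_epochs` object.
#' @param crop_start,crop_end window edges in seconds relative to the cue.
#' @return the cropped `eeg_epochs`, with `t_start` updated to `crop_start`.
#' @export
crop_epochs <- function(x, crop_start, crop_end) {
  validate_epochs(x)
  if (crop_end <= crop_start) stop("crop_end must exceed crop_start", call. = FALSE)
  t_end <- x$t_start + n_samples(x) / x$fs
  if (crop_start < x$t_start - 1e-9 || crop_end > t_end + 1e-9)
    stop(sprintf("crop window [%g, %g) outside recorded epoch [%g, %g)",
                 crop_start, crop_end, x$t_start, t_end), call. = FALSE)
  i0 <- round((crop_start - x$t_start) * x$fs)          # 0-based first sample
  n  <- round((crop_end - crop_start) * x$fs)
  y <- x
  y$data <- x$data[, , (i0 + 1L):(i0 + n), drop = FALSE]
  y$t_start <- crop_start
  y
}

#' Per-trial, per-channel z-score normalization
#'
#' Each (trial, channel) trace is standardized independently using its own
#' mean and unbiased (denominator `T - 1`) standard deviation, so baseline
#' offsets and amplitude scales of individual fragments never pool across
#' trials or channels. After the transform every trace has mean 0 and
#' unbiased SD 1; the operation is idempotent and invariant to per-trace
#' affine rescaling.
#'
#' @param x an `eeg_epochs` object with at least 2 samples per trial.
#' @param eps optional non-negative guard added to the SD. The default `0`
#'   makes a constant (zero-variance) trace a hard error identifying the
#'   offending (trial, channel) — silent epsilons mask broken channels.
#' @return the normalized `eeg_epochs`, with `normalized = TRUE`.
#' @export
zscore_epochs <- function(x, eps = 0) {
  validate_epochs(x)
  T <- n_samples(x)
  if (T < 2L) stop("z-scoring needs at least 2 samples per trial", call. = FALSE)
  out <- x$data
  for (i in seq_len(n_trials(x))) {
    m <- x$data[i, , , drop = TRUE]               # [channel, time]
    if (n_channels(x) == 1L) m <- matrix(m, 1L)
    mu <- rowMeans(m)
    sd_ <- sqrt(rowSums((m - mu)^2) / (T - 1))
    if (eps <= 0 && any(sd_ == 0)) {
      ch <- which(sd_ == 0)[1L]
      stop(sprintf("degenerate (constant) channel: trial %d, channel %s",
                   i, x$channel_names[ch]), call. = FALSE)
    }
    out[i, , ] <- (m - mu) / (sd_ + eps)
  }
  y <- x
  y$data <- out
  y$normalized <- TRUE
  y
}
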