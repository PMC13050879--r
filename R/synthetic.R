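#' Specification of a synthetic motor-imagery EEG dataset
#'
#' Describes labeled trials that mimic the statistical skeleton of
#' sensorimotor-rhythm motor imagery: pink (1/f^alpha) background noise on
#' every channel, plus a class-specific band-limited oscillation (a
#' Hann-windowed sinusoid at the class's rhythm frequency, e.g. mu ~10 Hz
#' or beta ~22 Hz) confined to that class's effect channels. Class
#' separability is controlled jointly by `snr` and `erd_depth`; both at
#' their floor make the class-conditional distributions identical.
#'
#' @param n_trials_per_class trials per class.
#' @param n_classes 2 or 4.
#' @param channels montage subset name (see [channel_subset()]) or explicit
#'   channel-name vector.
#' @param fs sampling rate in Hz (default 250).
#' @param duration trial length in seconds (default 4; `fs * duration` must
#'   be integral).
#' @param rhythm_freqs per-class oscillation frequency in Hz.
#' @param erd_channels list of per-class channel subsets carrying the
#'   effect; all must be members of `channels`.
#' @param erd_depth fractional amplitude of the class effect in `[0, 1]`.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param snr amplitude ratio of the class oscillation (RMS) to the
#'   unit-RMS background (>= 0).
#' @param seed integer seed; the generated set is a pure function of it.
#' @return a `synth_spec` list.
#' @export
mi_synth_spec <- function(n_trials_per_class = 72, n_classes = 2,
                          channels = "c3czc4_3", fs = 250, duration = 4,
                          rhythm_freqs = NULL, erd_channels = NULL,
                          erd_depth = 1, noise_exponent = 1, snr = 1,
                          seed = 1) {
  if (!n_classes %in% c(2L, 4L))
    stop("n_classes must be 2 or 4", call. = FALSE)
  chans <- if (length(channels) == 1L && channels %in% names(CHANNEL_SUBSETS))
    CHANNEL_SUBSETS[[channels]] else as.character(channels)
  if (abs(fs * duration - round(fs * duration)) > 1e-9)
    stop("fs * duration must be an integer sample count", call. = FALSE)
  if (is.null(rhythm_freqs))
    rhythm_freqs <- if (n_classes == 2L) c(10, 22) else c(10, 12, 22, 26)
  if (is.null(erd_channels)) {
    base <- list("C3", "C4", "Cz", c("C3", "C4"))
    erd_channels <- lapply(seq_len(n_classes), function(i) {
      found <- intersect(base[[i]], chans)
      if (length(found)) found else chans[1L + (i - 1L) %% length(chans)]
    })
  }
  for (ec in erd_channels)
    if (!all(ec %in% chans))
      stop("erd_channels must be a subset of channels", call. = FALSE)
  if (snr < 0) stop("snr must be >= 0", call. = FALSE)
  if (erd_depth < 0 || erd_depth > 1)
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_classes = as.integer(n_classes), channels = chans,
                 fs = fs, duration = duration, rhythm_freqs = rhythm_freqs,
                 erd_channels = erd_channels, erd_depth = erd_depth,
                 noise_exponent = noise_exponent, snr = snr,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# One trace of unit-RMS 1/f^alpha noise of length T via spectral shaping.
pink_noise <- function(T, alpha, rng) {
  w <- rng$norm(T)
  W <- stats::fft(w)
  f <- c(1, seq_len(T - 1L))          # DC handled separately
  scale <- f^(-alpha / 2)
  scale[1L] <- 0                      # remove DC
  # mirror-symmetric scaling keeps the inverse transform real
  half <- ceiling((T + 1L) / 2)
  if (half < T) scale[(half + 1L):T] <- scale[T + 1L - ((half + 1L):T) + 1L]
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / T
  s <- sqrt(mean(x^2))
  if (s == 0) x else x / s
}

#' Generate a synthetic motor-imagery EEG dataset
#'
#' @param spec a [mi_synth_spec()].
#' @return an `eeg_epochs` with balanced 0-based labels, fully determined
#'   by `spec$seed`.
#' @examples
#' x <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 4, seed = 7))
#' x
#' @export
simulate_mi_eeg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  T <- as.integer(round(spec$fs * spec$duration))
  C <- length(spec$channels)
  n <- spec$n_trials_per_class * spec$n_classes
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_trials_per_class)
  rng <- local_rng(derive_seed(spec$seed, "simulate"))
  tgrid <- (seq_len(T) - 1L) / spec$fs
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = T)))
  data <- array(0, c(n, C, T))
  for (i in seq_len(n)) {
    cl <- labels[i] + 1L
    for (c in seq_len(C))
      data[i, c, ] <- pink_noise(T, spec$noise_exponent, rng)
    amp <- spec$snr * spec$erd_depth
    for (ch in spec$erd_channels[[cl]]) {
      # phase is drawn whether or not the effect is active, so runs that
      # differ only in snr/erd_depth share an identical noise background
      phase <- rng$unif(1) * 2 * pi
      if (amp > 0) {
        osc <- hann * sin(2 * pi * spec$rhythm_freqs[cl] * tgrid + phase)
        osc <- osc / sqrt(mean(osc^2)) * amp   # effect RMS = snr * depth
        ci <- match(ch, spec$channels)
        data[i, ci, ] <- data[i, ci, ] + osc
      }
    }
  }
  eeg_epochs(data, labels, spec$fs, spec$channels, t_start = 0,
             meta = list(source = "synthetic", n_classes = spec$n_classes),
             normalized = FALSE)
}

#' Log band-power nearest-centroid baseline
#'
#' A deliberately simple reference classifier used to certify the
#' difficulty regime of a dataset: per trial it computes log mean
#' periodogram power in each (channel, band) cell, standardizes features,
#' and assigns held-out trials to the nearest class centroid under a
#' stratified 80/20 split.
#'
#' @param x an `eeg_epochs` object with >= 2 classes present.
#' @param bands named list of `c(low, high)` Hz bands (defaults to mu
#'   8-12 Hz and beta 13-30 Hz).
#' @param train_fraction fraction of trials used for the centroids.
#' @param seed split seed.
#' @return held-out accuracy in `[0, 1]`.
#' @export
bandpower_baseline <- function(x, bands = list(mu = c(8, 12),
                                               beta = c(13, 30)),
                               train_fraction = 0.8, seed = 1) {
  validate_epochs(x)
  if (length(unique(x$labels)) < 2L)
    stop("baseline needs at least 2 classes", call. = FALSE)
  T <- n_samples(x)
  freqs <- (seq_len(T) - 1L) * x$fs / T
  feats <- matrix(0, n_trials(x), n_channels(x) * length(bands))
  for (i in seq_len(n_trials(x))) {
    col <- 0L
    for (c in seq_len(n_channels(x))) {
      pw <- Mod(stats::fft(x$data[i, c, ]))^2 / T
      for (b in bands) {
        col <- col + 1L
        sel <- freqs >= b[1L] & freqs <= b[2L]
        feats[i, col] <- log(mean(pw[sel]) + 1e-12)
      }
    }
  }
  sds <- apply(feats, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate (zero-variance) band-power feature", call. = FALSE)
  feats <- scale(feats)
  rng <- local_rng(derive_seed(seed, "baseline"))
  tr <- stratified_take(x$labels, seq_len(n_trials(x)),
                        round(train_fraction * n_trials(x)), rng)
  te <- setdiff(seq_len(n_trials(x)), tr)
  classes <- sort(unique(x$labels[tr]))
  centroids <- t(vapply(classes, function(cl)
    colMeans(feats[tr[x$labels[tr] == cl], , drop = FALSE]),
    numeric(ncol(feats))))
  d2 <- vapply(seq_len(nrow(centroids)), function(k)
    rowSums(sweep(feats[te, , drop = FALSE], 2L, centroids[k, ])^2),
    numeric(length(te)))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == x$labels[te])
}
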