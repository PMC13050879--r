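#' Segmentation-and-reconstruction augmentation
#'
#' Each trial is cut into `n_segments` equal, temporally ordered slots
#' (e.g. 8 slots of 125 samples on a 1000-sample trial). New trials of a
#' class are assembled slot-by-slot: slot j of a new trial is slot j of a
#' uniformly chosen donor trial of the same class (drawn independently per
#' slot, with replacement), so the temporal order of slots is always
#' preserved and no slot ever blends two sources. Labels are inherited.
#'
#' @param x an `eeg_epochs` object (a training split).
#' @param n_segments number of slots `Ns`; must divide `n_samples` exactly.
#' @param multiplier new trials generated per original trial (>= 0).
#' @param seed integer RNG seed; the output is fully determined by it.
#' @return an `eeg_epochs` of `n_trials * multiplier` reconstructed trials.
#' @export
segment_and_reconstruct <- function(x, n_segments = 8, multiplier = 1,
                                    seed = 1) {
  validate_epochs(x)
  T <- n_samples(x)
  if (T %% n_segments != 0)
    stop(sprintf("n_samples (%d) not divisible by n_segments (%d)",
                 T, n_segments), call. = FALSE)
  if (multiplier < 0) stop("multiplier must be >= 0", call. = FALSE)
  seg_len <- T %/% n_segments
  n_new <- n_trials(x) * multiplier
  out <- array(0, c(n_new, n_channels(x), T))
  labs <- integer(n_new)
  rng <- local_rng(seed)
  pos <- 0L
  for (cl in sort(unique(x$labels))) {
    members <- which(x$labels == cl)
    if (length(members) == 0L) next
    for (r in seq_len(length(members) * multiplier)) {
      pos <- pos + 1L
      donors <- members[rng$int(length(members), n_segments)]
      for (j in seq_len(n_segments)) {
        sl <- ((j - 1L) * seg_len + 1L):(j * seg_len)
        out[pos, , sl] <- x$data[donors[j], , sl]
      }
      labs[pos] <- cl
    }
  }
  meta <- x$meta
  meta$n_classes <- n_classes(x)
  eeg_epochs(out[seq_len(pos), , , drop = FALSE], labs[seq_len(pos)],
             x$fs, x$channel_names, x$t_start, meta, x$normalized)
}

#' Add bounded Gaussian noise
#'
#' Draws elementwise `Normal(0, sigma^2)` noise, clips it to
#' `[-bound, bound]` (default `[-1, 1]`, meaningful on z-scored,
#' unit-variance data) and adds it to the signal. `sigma = 0` is the exact
#' identity; a fixed seed makes the noise field bit-reproducible.
#'
#' @param x an `eeg_epochs` object.
#' @param sigma noise standard deviation before clipping (>= 0).
#' @param bound absolute clip value (> 0).
#' @param seed integer RNG seed.
#' @return the noised `eeg_epochs`.
#' @export
add_bounded_noise <- function(x, sigma = 0.2, bound = 1, seed = 1) {
  validate_epochs(x)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (bound <= 0) stop("bound must be > 0", call. = FALSE)
  if (sigma == 0) return(x)
  rng <- local_rng(seed)
  g <- rng$norm(length(x$data)) * sigma
  g <- pmin(pmax(g, -bound), bound)
  y <- x
  y$data <- x$data + array(g, dim(x$data))
  y
}

#' Build the augmented training set
#'
#' Runs segmentation-and-reconstruction, injects bounded Gaussian noise into
#' the reconstructed trials only, mixes them with the originals and shuffles
#' the combined set. Per-class counts scale exactly by `1 + multiplier`.
#' Refuses to run on a split tagged as test data (`meta$split == "test"`) —
#' augmented samples must never derive from held-out trials.
#'
#' @param x an `eeg_epochs` training split.
#' @param n_segments slots per trial (default 8).
#' @param noise_sigma SD of the bounded noise (default 0.2).
#' @param noise_bound absolute noise cap (default 1).
#' @param multiplier reconstructed trials per original (default 1).
#' @param seed integer RNG seed driving reconstruction, noise and shuffle.
#' @return an `eeg_epochs` of `n_trials * (1 + multiplier)` trials.
#' @export
build_augmented_train_set <- function(x, n_segments = 8, noise_sigma = 0.2,
                                      noise_bound = 1, multiplier = 1,
                                      seed = 1) {
  validate_epochs(x)
  if (identical(x$meta$split, "test"))
    stop("refusing to augment a test split (leakage guard)", call. = FALSE)
  if (multiplier > 0) {
    recon <- segment_and_reconstruct(x, n_segments, multiplier,
                                     seed = derive_seed(seed, "recon"))
    recon <- add_bounded_noise(recon, noise_sigma, noise_bound,
                               seed = derive_seed(seed, "noise"))
    dat <- array(0, c(n_trials(x) + n_trials(recon), n_channels(x),
                      n_samples(x)))
    dat[seq_len(n_trials(x)), , ] <- x$data
    dat[n_trials(x) + seq_len(n_trials(recon)), , ] <- recon$data
    labs <- c(x$labels, recon$labels)
  } else {
    dat <- x$data
    labs <- x$labels
  }
  rng <- local_rng(derive_seed(seed, "shuffle"))
  ord <- rng$permute(length(labs))
  meta <- x$meta
  meta$n_classes <- n_classes(x)
  eeg_epochs(dat[ord, , , drop = FALSE], labs[ord], x$fs, x$channel_names,
             x$t_start, meta, x$normalized)
}
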