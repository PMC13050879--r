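#' Epoched multichannel EEG trials
#'
#' Container for a set of labeled, fixed-length EEG trials (epochs), the
#' common currency of every stage in the package: preprocessing,
#' augmentation, model fitting and evaluation all consume and return
#' `eeg_epochs` objects.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, amplitudes
#'   in microvolts (or normalized units once z-scored). All values must be
#'   finite.
#' @param labels integer vector of class indices, one per trial, taking
#'   values in `0 .. n_classes-1`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of 10-20-system electrode names,
#'   one per channel, in the row order of `data`'s second dimension.
#' @param t_start epoch start time in seconds relative to the task cue
#'   (default 0).
#' @param meta named list of free-form tags (subject, session, split, ...).
#' @param normalized logical; `TRUE` once per-trial per-channel z-scoring
#'   has been applied.
#'
#' @return An object of class `eeg_epochs`.
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 3 * 100), c(2, 3, 100)),
#'                 labels = c(0, 1), fs = 250,
#'                 channel_names = c("C3", "Cz", "C4"))
#' x
#' @export
eeg_epochs <- function(data, labels, fs, channel_names,
                       t_start = 0, meta = list(), normalized = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, time]", call. = FALSE)
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  x <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         t_start = as.numeric(t_start), meta = meta,
         normalized = isTRUE(normalized)),
    class = "eeg_epochs")
  validate_epochs(x)
  x
}

#' Validate the invariants of an `eeg_epochs` object
#'
#' Checks finiteness, label/channel-count agreement, label range and a
#' positive sampling rate. Called by every constructor and on bundle load.
#'
#' @param x an `eeg_epochs` object.
#' @return `x`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
validate_epochs <- function(x) {
  d <- dim(x$data)
  if (length(x$labels) != d[1L])
    stop(sprintf("labels length (%d) != n_trials (%d)",
                 length(x$labels), d[1L]), call. = FALSE)
  if (length(x$channel_names) != d[2L])
    stop(sprintf("channel_names length (%d) != n_channels (%d)",
                 length(x$channel_names), d[2L]), call. = FALSE)
  if (!is.finite(x$fs) || x$fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  if (length(x$data) && !all(is.finite(x$data)))
    stop("data contains non-finite values", call. = FALSE)
  if (d[1L] > 0L && any(x$labels < 0L))
    stop("labels must be non-negative 0-based class indices", call. = FALSE)
  invisible(x)
}

n_trials   <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_samples  <- function(x) dim(x$data)[3L]

#' Number of classes represented in an epoch set
#'
#' Labels are 0-based indices, so the class count is `max(label) + 1` (or a
#' `n_classes` entry in `meta`, which wins when present so that subsets with
#' absent classes keep the original cardinality).
#'
#' @param x an `eeg_epochs` object.
#' @return integer class count.
#' @export
n_classes <- function(x) {
  if (!is.null(x$meta$n_classes)) return(as.integer(x$meta$n_classes))
  if (length(x$labels) == 0L) return(0L)
  max(x$labels) + 1L
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  t_start: %g s, %s\n", x$t_start,
              if (x$normalized) "z-scored" else "raw units (uV)"))
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:(n_classes(x) - 1L)))
    cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = ", "), "\n")
  }
  cat("  channels:", paste(utils::head(x$channel_names, 8L), collapse = ", "),
      if (length(x$channel_names) > 8L) "...\n" else "\n")
  invisible(x)
}

#' @export
summary.eeg_epochs <- function(object, ...) {
  print(object)
  if (length(object$data)) {
    cat(sprintf("  amplitude range: [%.3g, %.3g]\n",
                min(object$data), max(object$data)))
  }
  invisible(object)
}

#' Take a subset of trials
#'
#' @param x an `eeg_epochs` object.
#' @param idx integer vector of trial indices (1-based).
#' @return an `eeg_epochs` holding the selected trials, in `idx` order.
#' @export
subset_trials <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (any(idx < 1L) || any(idx > n_trials(x))))
    stop("trial index out of range", call. = FALSE)
  meta <- x$meta
  meta$n_classes <- n_classes(x)
  eeg_epochs(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs,
             x$channel_names, x$t_start, meta, x$normalized)
}

# --- montage and nested channel subsets -------------------------------------

# Full 22-electrode montage of the standard 4-class MI recording layout.
MONTAGE_22 <- c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
                "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                "CP3", "CP1", "CPz", "CP2", "CP4",
                "P1", "Pz", "P2", "POz")

CHANNEL_SUBSETS <- local({
  s3  <- c("C3", "Cz", "C4")
  s9  <- c(s3, "Fz", "Pz", "C1", "C2", "FCz", "CPz")
  s13 <- c(s9, "FC1", "FC2", "CP1", "CP2")
  s17 <- c(s13, "FC3", "FC4", "CP3", "CP4")
  list(c3czc4_3 = s3, central_9 = s9, central_13 = s13,
       central_17 = s17, all_22 = MONTAGE_22)
})

#' Named electrode subsets of the 22-channel motor-cortex montage
#'
#' The hierarchy expands outward from the central electrodes C3/Cz/C4 in
#' strictly nested rings: 3 < 9 < 13 < 17 < 22 channels.
#'
#' @param name one of `"c3czc4_3"`, `"central_9"`, `"central_13"`,
#'   `"central_17"`, `"all_22"`.
#' @return character vector of electrode names in subset order.
#' @examples
#' channel_subset("c3czc4_3")
#' @export
channel_subset <- function(name = c("c3czc4_3", "central_9", "central_13",
                                    "central_17", "all_22")) {
  name <- match.arg(name)
  CHANNEL_SUBSETS[[name]]
}

#' Restrict an epoch set to a channel subset
#'
#' Slices (and reorders) the channel dimension to match a named subset or an
#' explicit vector of electrode names. Labels and every other field are
#' unchanged.
#'
#' @param x an `eeg_epochs` object.
#' @param subset a subset name accepted by [channel_subset()], or a character
#'   vector of channel names, all of which must be present in `x`.
#' @return the reduced `eeg_epochs`.
#' @export
select_channels <- function(x, subset) {
  chans <- if (length(subset) == 1L && subset %in% names(CHANNEL_SUBSETS))
    CHANNEL_SUBSETS[[subset]] else as.character(subset)
  pos <- match(chans, x$channel_names)
  if (anyNA(pos))
    stop("channels not present in epochs: ",
         paste(chans[is.na(pos)], collapse = ", "), call. = FALSE)
  meta <- x$meta
  meta$n_classes <- if (length(x$labels)) n_classes(x) else NULL
  eeg_epochs(x$data[, pos, , drop = FALSE], x$labels, x$fs,
             chans, x$t_start, meta, x$normalized)
}
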