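#' Within-session training protocol settings
#'
#' One recording session's trials are shuffled and split 80/20 into a
#' training pool and a held-out test set; 20% of the pool becomes the
#' validation set used for model selection. The split/train/evaluate cycle
#' is repeated `n_repeats` times with independent stratified shuffles and
#' the mean test result is reported.
#'
#' @param test_fraction held-out fraction of all trials (default 0.2).
#' @param val_fraction_of_train validation fraction of the training pool
#'   (default 0.2).
#' @param n_repeats independent split repetitions (default 5).
#' @param batch_size,max_epochs,lr optimizer settings (defaults 32, 100,
#'   0.001; cosine annealing over `max_epochs`).
#' @param augment list of [build_augmented_train_set()] settings applied to
#'   the training split only (`NULL` disables augmentation).
#' @param seed global protocol seed; repeat `r` derives its own streams.
#' @return a `train_protocol` list.
#' @export
train_protocol <- function(test_fraction = 0.2, val_fraction_of_train = 0.2,
                           n_repeats = 5, batch_size = 32, max_epochs = 100,
                           lr = 1e-3,
                           augment = list(n_segments = 8, noise_sigma = 0.2,
                                          multiplier = 1),
                           seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction_of_train > 0, val_fraction_of_train < 1,
            batch_size >= 1)
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 n_repeats = as.integer(n_repeats),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 augment = augment, seed = as.integer(seed)),
            class = "train_protocol")
}

# Allocate a stratified sample of exactly `target` indices across classes,
# proportional with largest-remainder rounding.
stratified_take <- function(labels, pool, target, rng) {
  classes <- sort(unique(labels[pool]))
  counts <- vapply(classes, function(cl) sum(labels[pool] == cl), 0L)
  quota <- counts * target / length(pool)
  take <- floor(quota)
  rem <- target - sum(take)
  if (rem > 0) {
    extra <- order(-(quota - take))[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  out <- integer(0)
  for (ci in seq_along(classes)) {
    members <- pool[labels[pool] == classes[ci]]
    pick <- members[rng$permute(length(members))[seq_len(take[ci])]]
    out <- c(out, pick)
  }
  sort(out)
}

#' Stratified within-session train/validation/test split
#'
#' Produces three disjoint `eeg_epochs` covering all trials: a test set of
#' `round(test_fraction * n)` trials, a validation set of
#' `round(val_fraction_of_train * |pool|)` trials and the remaining
#' training set, each stratified by class. Fully determined by
#' `(protocol$seed, repeat_index)`.
#'
#' @param x an `eeg_epochs` object.
#' @param protocol a [train_protocol()].
#' @param repeat_index which repetition's split to draw (1-based).
#' @return list with elements `train`, `val`, `test` (each tagged via
#'   `meta$split`) and `indices` (the 1-based trial indices of each).
#' @export
split_within_session <- function(x, protocol, repeat_index = 1) {
  validate_epochs(x)
  n <- n_trials(x)
  counts <- table(x$labels)
  if (any(counts < 5))
    stop("stratification needs at least 5 trials per class", call. = FALSE)
  rng <- local_rng(derive_seed(protocol$seed,
                               paste0("split", repeat_index)))
  all_idx <- seq_len(n)
  test <- stratified_take(x$labels, all_idx, round(protocol$test_fraction * n),
                          rng)
  pool <- setdiff(all_idx, test)
  val <- stratified_take(x$labels, pool,
                         round(protocol$val_fraction_of_train * length(pool)),
                         rng)
  train <- setdiff(pool, val)
  tag <- function(idx, split) {
    y <- subset_trials(x, idx)
    y$meta$split <- split
    y
  }
  list(train = tag(train, "train"), val = tag(val, "val"),
       test = tag(test, "test"),
       indices = list(train = train, val = val, test = test))
}

#' Evaluate a fitted decoder on a held-out test set
#'
#' @param model a fitted `mi_decoder`.
#' @param test an `eeg_epochs` test set.
#' @return an `eval_report`: confusion matrix (rows = true class, columns =
#'   predicted), accuracy (`trace / n`), Cohen's kappa, and `n_test`.
#' @export
evaluate <- function(model, test) {
  validate_epochs(test)
  if (n_trials(test) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict(model, test, type = "class")
  ncl <- model$config$n_classes
  confusion <- table(factor(test$labels, levels = 0:(ncl - 1L)),
                     factor(pred, levels = 0:(ncl - 1L)))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("true", "predicted")
  structure(list(confusion = confusion,
                 accuracy = accuracy_from_confusion(confusion),
                 kappa = kappa_from_confusion(confusion),
                 n_test = n_trials(test)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy %.4f  kappa %.4f\n",
              x$n_test, x$accuracy, x$kappa))
  if (!is.null(x$per_repeat))
    cat(sprintf("  per-repeat accuracy: %s (mean %.4f, sd %.4f)\n",
                paste(sprintf("%.3f", x$per_repeat), collapse = ", "),
                mean(x$per_repeat), stats::sd(x$per_repeat)))
  print(x$confusion)
  invisible(x)
}

#' Accuracy from a confusion matrix
#'
#' Fraction of correctly classified trials: the diagonal sum over the total
#' (the multiclass generalization of `(TP + TN) / (TP + TN + FP + FN)`).
#'
#' @param confusion square count matrix, rows = true class.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)`, with the expected
#' agreement `P_e` computed from the row/column marginals when a confusion
#' matrix is given.
#'
#' @param po observed agreement `P_o`, or a square confusion matrix.
#' @param pe expected chance agreement `P_e` (ignored when `po` is a
#'   matrix).
#' @return kappa (`<= 1`; 1 iff agreement is perfect).
#' @examples
#' cohen_kappa(0.9, 0.5)  # 0.8
#' @export
cohen_kappa <- function(po, pe = NULL) {
  if (is.matrix(po)) return(kappa_from_confusion(po))
  (po - pe) / (1 - pe)
}

kappa_from_confusion <- function(confusion) {
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Paired Wilcoxon signed-rank comparison of two decoders
#'
#' Two-sided exact signed-rank test on paired per-subject (or per-repeat)
#' accuracies, the standard nonparametric test for comparing decoders
#' across subjects. Significance is conventionally read at 0.05 and 0.01.
#'
#' @param acc_a,acc_b paired numeric vectors of equal length (>= 5).
#' @return the two-sided p-value. All-zero differences give `p = 1` with a
#'   warning (no signal to test).
#' @export
wilcoxon_compare <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(acc_a) < 5)
    stop("need at least 5 pairs", call. = FALSE)
  d <- acc_a - acc_b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(acc_a, acc_b, paired = TRUE, exact = TRUE)$p.value)
}

#' Run the full within-session protocol
#'
#' For each of `n_repeats` stratified splits: z-scored training trials are
#' augmented (training split only — augmentation never sees validation or
#' test trials, asserted on indices each repeat), the decoder is fitted
#' with validation-based model selection, and test accuracy/kappa are
#' computed. Reports the pooled confusion matrix and per-repeat
#' accuracies.
#'
#' @param x an `eeg_epochs` session (already preprocessed).
#' @param protocol a [train_protocol()].
#' @param config a [model_config()] shared by all repeats (default: derived
#'   from the data geometry).
#' @param verbose print per-repeat progress.
#' @return an `eval_report` with `per_repeat` accuracies, `per_repeat_kappa`
#'   and the summed confusion matrix.
#' @export
run_protocol <- function(x, protocol = train_protocol(), config = NULL,
                         verbose = FALSE) {
  validate_epochs(x)
  if (is.null(config))
    config <- model_config(C = n_channels(x), T = n_samples(x),
                           n_classes = n_classes(x), fs = x$fs)
  accs <- numeric(protocol$n_repeats)
  kaps <- numeric(protocol$n_repeats)
  conf_sum <- NULL
  for (r in seq_len(protocol$n_repeats)) {
    sp <- split_within_session(x, protocol, r)
    stopifnot(length(intersect(sp$indices$train, sp$indices$test)) == 0,
              length(intersect(sp$indices$val, sp$indices$test)) == 0,
              length(intersect(sp$indices$train, sp$indices$val)) == 0)
    tr <- sp$train
    if (!is.null(protocol$augment)) {
      a <- protocol$augment
      tr <- build_augmented_train_set(
        tr, n_segments = a$n_segments %||% 8,
        noise_sigma = a$noise_sigma %||% 0.2,
        multiplier = a$multiplier %||% 1,
        seed = derive_seed(protocol$seed, paste0("augment", r)))
    }
    fit <- mi_decoder(tr, config = config, val = sp$val,
                      epochs = protocol$max_epochs,
                      batch_size = protocol$batch_size, lr = protocol$lr,
                      seed = derive_seed(protocol$seed, paste0("fit", r)),
                      verbose = FALSE)
    rep_eval <- evaluate(fit, sp$test)
    accs[r] <- rep_eval$accuracy
    kaps[r] <- rep_eval$kappa
    conf_sum <- if (is.null(conf_sum)) rep_eval$confusion
                else conf_sum + rep_eval$confusion
    if (verbose)
      message(sprintf("repeat %d/%d: accuracy %.3f kappa %.3f",
                      r, protocol$n_repeats, accs[r], kaps[r]))
  }
  structure(list(confusion = conf_sum,
                 accuracy = mean(accs), kappa = mean(kaps),
                 per_repeat = accs, per_repeat_kappa = kaps,
                 n_test = sum(conf_sum)),
            class = "eval_report")
}
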