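#' Fit the motor-imagery decoder
#'
#' Trains the convolutional sparse-attention network on a set of labeled
#' EEG trials with Adam under a cosine-annealed learning rate. When a
#' validation set is supplied, validation accuracy is recorded after every
#' epoch and the returned model carries the weights of the best-validation
#' epoch (ties resolve to the earliest); otherwise the final weights are
#' kept.
#'
#' @param x an `eeg_epochs` training set (typically z-scored and augmented).
#'   Refuses a set tagged as test data.
#' @param config a [model_config()]; defaults to the standard architecture
#'   for `x`'s geometry.
#' @param val optional `eeg_epochs` validation set.
#' @param epochs maximum training epochs.
#' @param batch_size trials per optimization step.
#' @param lr peak Adam learning rate; annealed to 0 over `epochs` by
#'   `lr * 0.5 * (1 + cos(pi * epoch / epochs))` (no warm restarts).
#' @param seed integer seed controlling initialization, batch order and
#'   dropout; a fixed seed makes the fit bit-reproducible.
#' @param verbose print per-epoch progress.
#' @return an object of class `mi_decoder`: list with `params` (best
#'   weights), `state` (batch-norm running statistics), `config`, `history`
#'   (per-epoch data frame), `best_epoch` and `n_parameters`.
#' @seealso [predict.mi_decoder()], [evaluate()], [run_protocol()]
#' @export
mi_decoder <- function(x, config = NULL, val = NULL, epochs = 100,
                       batch_size = 32, lr = 1e-3, seed = 1,
                       verbose = FALSE) {
  validate_epochs(x)
  if (identical(x$meta$split, "test"))
    stop("refusing to train on a test split", call. = FALSE)
  if (n_trials(x) < 1L) stop("empty training set", call. = FALSE)
  if (is.null(config))
    config <- model_config(C = n_channels(x), T = n_samples(x),
                           n_classes = n_classes(x), fs = x$fs)
  if (config$C != n_channels(x) || config$T != n_samples(x))
    stop("config geometry does not match the data", call. = FALSE)

  params <- init_params(config, seed)
  state <- init_state(config)
  skel <- params
  theta <- flatten_params(params)
  mt <- numeric(length(theta))
  vt <- numeric(length(theta))
  adam_t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  n <- n_trials(x)
  n_batch <- max(1L, ceiling(n / batch_size))
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_accuracy = numeric())
  best <- list(theta = theta, state = state, epoch = 0L, val = -Inf)
  drop_rng <- local_rng(derive_seed(seed, "dropout"))

  for (ep in seq_len(epochs)) {
    lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    ord <- local_rng(derive_seed(seed, paste0("order", ep)))$permute(n)
    ep_loss <- 0
    for (bi in seq_len(n_batch)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      Xb <- epochs_to_batch(x, idx)
      yb <- x$labels[idx]
      params <- unflatten_params(theta, skel)
      fw <- apc_forward(params, state, Xb, config, train = TRUE,
                        rng = drop_rng)
      state <- fw$state
      ep_loss <- ep_loss + cross_entropy_loss(fw$probs, yb) * length(idx)
      onehot <- matrix(0, length(idx), config$n_classes)
      onehot[cbind(seq_along(idx), yb + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / length(idx)
      grads <- apc_backward(params, fw$cache, dlogits, config)
      gvec <- flatten_params(grads)
      adam_t <- adam_t + 1L
      mt <- beta1 * mt + (1 - beta1) * gvec
      vt <- beta2 * vt + (1 - beta2) * gvec * gvec
      mhat <- mt / (1 - beta1^adam_t)
      vhat <- vt / (1 - beta2^adam_t)
      theta <- theta - lr_ep * mhat / (sqrt(vhat) + adam_eps)
    }
    ep_loss <- ep_loss / n
    val_acc <- NA_real_
    if (!is.null(val) && n_trials(val) > 0L) {
      params <- unflatten_params(theta, skel)
      val_acc <- mean(predict_labels(params, state, config, val) ==
                        val$labels)
      if (val_acc > best$val) {
        best <- list(theta = theta, state = state, epoch = ep, val = val_acc)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr_ep,
                                   train_loss = ep_loss,
                                   val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.3f", ep, ep_loss,
                      if (is.na(val_acc)) NA else val_acc))
  }

  if (is.null(val) || best$epoch == 0L)
    best <- list(theta = theta, state = state, epoch = nrow(hist),
                 val = NA_real_)
  out <- structure(
    list(params = unflatten_params(best$theta, skel), state = best$state,
         config = config, history = hist, best_epoch = best$epoch,
         classes = seq_len(config$n_classes) - 1L,
         n_parameters = length(theta), seed = seed),
    class = "mi_decoder")
  out
}

# [trial, channel, time] -> time-major batch [T, B, C]
epochs_to_batch <- function(x, idx) {
  aperm(x$data[idx, , , drop = FALSE], c(3L, 1L, 2L))
}

predict_labels <- function(params, state, cfg, x, chunk = 64L) {
  max.col(predict_probs(params, state, cfg, x, chunk)) - 1L
}

predict_probs <- function(params, state, cfg, x, chunk = 64L) {
  n <- n_trials(x)
  probs <- matrix(0, n, cfg$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- apc_forward(params, state, epochs_to_batch(x, idx), cfg,
                      train = FALSE)
    probs[idx, ] <- fw$probs
  }
  probs
}

#' Predict classes or class probabilities for new trials
#'
#' Runs the fitted network in evaluation mode (batch-norm running
#' statistics, no dropout), so repeated calls on the same data are
#' bit-identical.
#'
#' @param object a fitted `mi_decoder`.
#' @param newdata an `eeg_epochs` object with the geometry the model was
#'   trained on.
#' @param type `"class"` for 0-based hard labels, `"prob"` for the
#'   `[n_trials, n_classes]` probability matrix.
#' @param ... unused.
#' @return integer labels or a probability matrix.
#' @export
predict.mi_decoder <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  validate_epochs(newdata)
  if (n_channels(newdata) != object$config$C ||
      n_samples(newdata) != object$config$T)
    stop(sprintf("newdata is %d ch x %d samples; model expects %d x %d",
                 n_channels(newdata), n_samples(newdata),
                 object$config$C, object$config$T), call. = FALSE)
  if (type == "prob")
    predict_probs(object$params, object$state, object$config, newdata)
  else predict_labels(object$params, object$state, object$config, newdata)
}

#' @export
print.mi_decoder <- function(x, ...) {
  cat("<mi_decoder> fitted motor-imagery EEG decoder\n")
  print(x$config)
  cat(sprintf("  %d learnable parameters; trained %d epochs",
              x$n_parameters, nrow(x$history)))
  if (!is.na(x$history$val_accuracy[nrow(x$history)]) || x$best_epoch > 0)
    cat(sprintf(" (best validation epoch %d)", x$best_epoch))
  cat("\n")
  invisible(x)
}

#' @export
summary.mi_decoder <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss: %.4f\n", h$train_loss[nrow(h)]))
  if (any(!is.na(h$val_accuracy)))
    cat(sprintf("  best validation accuracy: %.3f (epoch %d)\n",
                max(h$val_accuracy, na.rm = TRUE), object$best_epoch))
  bd <- attr(count_parameters(object$config), "breakdown")
  cat("  parameters by module:\n")
  for (m in names(bd)) cat(sprintf("    %-10s %6d\n", m, bd[[m]]))
  invisible(object)
}

#' @export
coef.mi_decoder <- function(object, ...) object$params

#' Plot the training history of a fitted decoder
#'
#' Training loss (left axis) and, when recorded, validation accuracy
#' (right axis) per epoch.
#'
#' @param x a fitted `mi_decoder`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mi_decoder <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$val_accuracy))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_accuracy, type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation accuracy", side = 4, line = 2.5)
    graphics::legend("right", c("train loss", "val accuracy"),
                     lty = c(1, 2), col = c(1, 2), bty = "n")
  }
  invisible(x)
}
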