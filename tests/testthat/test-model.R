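test_that("the shape chain holds for the standard 4-class configuration", {
  cfg <- model_config(C = 22, T = 1000, n_classes = 4)
  expect_equal(cfg$L1, 13L)                     # floor(1000 / 75)
  expect_equal(cfg$L2, 13L)                     # floor(3*13 / 3)
  expect_equal(cfg$partition$m, 10L)            # window 4, stride 1
  expect_equal(cfg$sat$d_model, cfg$F2)
  expect_equal(cfg$temporal_kernels, c(125L, 63L, 31L))

  x <- make_epochs(n = 32, C = 22, T = 1000, n_cls = 4,
                   channel_names = channel_subset("all_22"), seed = 12)
  params <- mieeg:::init_params(cfg, 1)
  fw <- mieeg:::apc_forward(params, mieeg:::init_state(cfg),
                            mieeg:::epochs_to_batch(x, 1:32), cfg)
  expect_equal(dim(fw$probs), c(32L, 4L))
  expect_equal(rowSums(fw$probs), rep(1, 32), tolerance = 1e-6)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(C = 3, T = 50, n_classes = 2, pool1 = 75), "pool1")
  expect_error(sat_config(d_model = 32, n_heads = 5), "divisible")
  expect_error(model_config(C = 3, T = 1000, n_classes = 2,
                            sat = sat_config(d_model = 16)), "d_model")
})

test_that("evaluation-mode forward is a pure function of weights and input", {
  cfg <- tiny_config()
  x <- tiny_epochs(n = 5)
  params <- mieeg:::init_params(cfg, 2)
  st <- mieeg:::init_state(cfg)
  X <- mieeg:::epochs_to_batch(x, 1:5)
  p1 <- mieeg:::apc_forward(params, st, X, cfg)$probs
  p2 <- mieeg:::apc_forward(params, st, X, cfg)$probs
  expect_identical(p1, p2)
})

test_that("AFR interaction gives every branch the full branch sum", {
  a <- matrix(as.numeric(1:6), 3); b <- matrix(0, 3, 2); cc <- matrix(-1, 3, 2)
  out <- mieeg:::afr_interaction(list(a, b, cc))
  expect_identical(out[[1]], a + b + cc)
  expect_identical(out[[2]], out[[1]])
  expect_identical(out[[3]], out[[1]])
  out2 <- mieeg:::afr_interaction(list(a, b * 0, cc * 0))
  expect_identical(out2[[2]], a)
})

test_that("CBAM preserves shape, gates in (0,1), and zero maps to zero", {
  set.seed(40)
  L <- 7; B <- 3; F2 <- 8
  p <- list(W1 = matrix(rnorm(F2 * 2), F2, 2), b1 = numeric(2),
            W2 = matrix(rnorm(2 * F2), 2, F2), b2 = numeric(F2),
            Wsp = matrix(rnorm(6), 2, 3), bsp = 0)
  S <- matrix(rnorm(L * B * F2), L * B, F2)
  out <- mieeg:::cbam_fw(S, p, L, B, F2)
  expect_equal(dim(out$out), dim(S))
  expect_true(all(out$cache$wc > 0 & out$cache$wc < 1))
  expect_true(all(out$cache$ws > 0 & out$cache$ws < 1))

  z <- mieeg:::cbam_fw(matrix(0, L * B, F2), p, L, B, F2)
  expect_equal(z$cache$wc, matrix(0.5, B, F2))    # sigmoid(0) everywhere
  expect_equal(as.vector(z$cache$ws), rep(0.5, L * B))
  expect_equal(z$out, matrix(0, L * B, F2))

  # distinct per-branch parameters recalibrate the shared input differently
  p2 <- p
  p2$W1 <- matrix(rnorm(F2 * 2, sd = 2), F2, 2)
  out2 <- mieeg:::cbam_fw(S, p2, L, B, F2)
  expect_false(isTRUE(all.equal(out$out, out2$out)))
})

test_that("classifier probabilities are a valid distribution", {
  cfg <- tiny_config(n_classes = 3)
  x <- tiny_epochs(n = 4, cfg = tiny_config(n_classes = 3))
  params <- mieeg:::init_params(cfg, 5)
  fw <- mieeg:::apc_forward(params, mieeg:::init_state(cfg),
                            mieeg:::epochs_to_batch(x, 1:4), cfg)
  expect_equal(rowSums(fw$probs), rep(1, 4), tolerance = 1e-6)
  expect_equal(ncol(fw$probs), 3L)

  # zero classifier weights: exactly uniform regardless of the features
  params$clf$W[] <- 0
  params$clf$b[] <- 0
  fw0 <- mieeg:::apc_forward(params, mieeg:::init_state(cfg),
                             mieeg:::epochs_to_batch(x, 1:4), cfg)
  expect_equal(fw0$probs, matrix(1 / 3, 4, 3), tolerance = 1e-12)
})

test_that("cross-entropy matches the closed forms and a loop oracle", {
  perfect <- diag(4)[c(1, 3), ]
  expect_equal(cross_entropy_loss(perfect, c(0, 2)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy_loss(matrix(0.25, 2, 4), c(1, 3)), log(4),
               tolerance = 1e-12)
  set.seed(9)
  probs <- matrix(stats::runif(5 * 3), 5, 3)
  probs <- probs / rowSums(probs)
  y <- c(0L, 2L, 1L, 1L, 0L)
  oracle <- 0
  for (i in 1:5) {
    onehot <- numeric(3); onehot[y[i] + 1] <- 1
    oracle <- oracle - sum(onehot * log(probs[i, ]))
  }
  expect_equal(cross_entropy_loss(probs, y), oracle / 5, tolerance = 1e-12)
})

test_that("parameter counts respond only to the modules they should", {
  base <- model_config(C = 22, T = 1000, n_classes = 4)
  n0 <- count_parameters(base)
  b0 <- attr(n0, "breakdown")

  wide <- model_config(C = 22, T = 1000, n_classes = 4, F2 = 64,
                       sat = sat_config(d_model = 64))
  expect_gt(count_parameters(wide), n0)

  fewer_ch <- model_config(C = 3, T = 1000, n_classes = 4)
  bc <- attr(count_parameters(fewer_ch), "breakdown")
  expect_lt(bc[["stconv"]], b0[["stconv"]])
  same <- setdiff(names(b0), "stconv")
  expect_identical(bc[same], b0[same])

  two_cls <- model_config(C = 22, T = 1000, n_classes = 2)
  b2 <- attr(count_parameters(two_cls), "breakdown")
  expect_lt(b2[["classifier"]], b0[["classifier"]])
  expect_identical(b2[setdiff(names(b0), "classifier")],
                   b0[setdiff(names(b0), "classifier")])
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- tiny_config(n_classes = 3, sat_layers = 2)
  set.seed(42)
  B <- 3
  X <- array(rnorm(cfg$T * cfg$C * B), c(cfg$T, B, cfg$C))
  y <- c(0L, 1L, 2L)
  params <- mieeg:::init_params(cfg, 7)
  skel <- params
  theta <- mieeg:::flatten_params(params)

  loss_at <- function(th) {
    p <- mieeg:::unflatten_params(th, skel)
    fw <- mieeg:::apc_forward(p, mieeg:::init_state(cfg), X, cfg,
                              train = TRUE)
    cross_entropy_loss(fw$probs, y)
  }
  fw <- mieeg:::apc_forward(params, mieeg:::init_state(cfg), X, cfg,
                            train = TRUE)
  onehot <- matrix(0, B, 3)
  onehot[cbind(1:B, y + 1)] <- 1
  gvec <- mieeg:::flatten_params(
    mieeg:::apc_backward(params, fw$cache, (fw$probs - onehot) / B, cfg))

  # positional-encoding gradient participates in backpropagation
  grads <- mieeg:::apc_backward(params, fw$cache, (fw$probs - onehot) / B,
                                cfg)
  expect_gt(max(abs(grads$pae$pos)), 0)

  eps <- 1e-6
  set.seed(1)
  idx <- sort(sample(length(theta), 80))
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - gvec[idx])), 1e-6)
})

test_that("checkpoints round-trip weights and predictions exactly", {
  cfg <- tiny_config()
  x <- tiny_epochs(n = 8)
  fit <- mi_decoder(x, config = cfg, epochs = 2, batch_size = 4, seed = 3)
  p <- withr::local_tempdir()
  save_checkpoint(fit, file.path(p, "ck"))
  back <- load_checkpoint(file.path(p, "ck"))
  expect_identical(mieeg:::flatten_params(back$params),
                   mieeg:::flatten_params(fit$params))
  expect_identical(predict(back, x, type = "prob"),
                   predict(fit, x, type = "prob"))
})
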