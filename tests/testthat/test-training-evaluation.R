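test_that("within-session splits have the protocol arithmetic", {
  x <- make_epochs(n = 100, C = 2, T = 40, n_cls = 2, seed = 15)
  proto <- train_protocol(seed = 3)
  sp <- split_within_session(x, proto, 1)
  expect_length(sp$indices$test, 20L)     # round(0.2 * 100)
  expect_length(sp$indices$val, 16L)      # round(0.2 * 80)
  expect_length(sp$indices$train, 64L)
  # partition property
  all_idx <- sort(c(sp$indices$train, sp$indices$val, sp$indices$test))
  expect_identical(all_idx, 1:100)
  # stratification: balanced classes stay balanced
  expect_equal(as.vector(table(sp$test$labels)), c(10, 10))
  expect_identical(sp$test$meta$split, "test")

  # deterministic in (seed, repeat); different repeats differ
  sp2 <- split_within_session(x, proto, 1)
  expect_identical(sp2$indices, sp$indices)
  sp3 <- split_within_session(x, proto, 2)
  expect_false(identical(sp3$indices$test, sp$indices$test))

  few <- make_epochs(n = 8, C = 2, T = 40, n_cls = 2)
  expect_error(split_within_session(few, proto, 1), "5 trials")
})

test_that("zero learning rate leaves the weights unchanged", {
  cfg <- tiny_config()
  x <- tiny_epochs(n = 8)
  # full-batch so per-epoch batch statistics are identical too
  fit <- mi_decoder(x, config = cfg, epochs = 3, batch_size = 8, lr = 0,
                    seed = 6)
  init <- mieeg:::init_params(cfg, 6)
  expect_identical(mieeg:::flatten_params(fit$params),
                   mieeg:::flatten_params(init))
  expect_equal(length(unique(round(fit$history$train_loss, 10))), 1L)
})

test_that("fitting is seed-deterministic and selects the best-val epoch", {
  cfg <- tiny_config()
  x <- tiny_epochs(n = 12, seed = 21)
  val <- tiny_epochs(n = 6, seed = 22)
  f1 <- mi_decoder(x, config = cfg, val = val, epochs = 4, batch_size = 4,
                   seed = 9)
  f2 <- mi_decoder(x, config = cfg, val = val, epochs = 4, batch_size = 4,
                   seed = 9)
  expect_identical(mieeg:::flatten_params(f1$params),
                   mieeg:::flatten_params(f2$params))
  expect_identical(f1$history, f2$history)

  # best-val contract: the kept epoch's accuracy is the running maximum,
  # and ties resolve to the earliest epoch
  va <- f1$history$val_accuracy
  expect_equal(f1$best_epoch, which.max(va))
  expect_gte(va[f1$best_epoch], max(va))

  expect_error(mi_decoder(subset_trials(x, integer(0)), config = cfg),
               "empty")
  xt <- x
  xt$meta$split <- "test"
  expect_error(mi_decoder(xt, config = cfg), "test split")
})

test_that("evaluation metrics match their closed forms", {
  expect_equal(cohen_kappa(0.9, 0.5), 0.8)
  conf <- matrix(c(3, 1, 0, 2), 2)              # rows true, cols predicted
  expect_equal(accuracy_from_confusion(conf), 5 / 6)
  expect_equal(cohen_kappa(conf),
               (5 / 6 - (3 * 4 + 3 * 2) / 36) / (1 - (3 * 4 + 3 * 2) / 36))

  perfect <- diag(c(7, 5))
  expect_equal(accuracy_from_confusion(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)

  # kappa == 1 iff the confusion matrix is diagonal (n > 0)
  off <- perfect
  off[1, 2] <- 1
  expect_lt(cohen_kappa(off), 1)
})

test_that("evaluate builds the confusion matrix with true rows", {
  cfg <- tiny_config()
  x <- tiny_epochs(n = 10, seed = 30)
  fit <- mi_decoder(x, config = cfg, epochs = 1, batch_size = 4, seed = 2)
  ev <- evaluate(fit, x)
  expect_equal(sum(ev$confusion), 10)
  expect_equal(as.vector(rowSums(ev$confusion)),
               as.vector(table(factor(x$labels, levels = 0:1))))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 10)
  # repeated evaluation of a fixed model is bit-identical
  ev2 <- evaluate(fit, x)
  expect_identical(ev2$confusion, ev$confusion)
  expect_error(evaluate(fit, subset_trials(x, integer(0))), "empty")
})

test_that("Wilcoxon comparison matches the exact sign-flip distribution", {
  a <- c(81.2, 77.5, 90.1, 68.3, 74.9, 83.0, 79.4, 85.7, 72.2)
  b <- a + 10                                    # constant shift, no ties
  p <- wilcoxon_compare(a, b)

  # oracle: enumerate all 2^9 sign assignments of the rank sum
  d <- abs(b - a) + seq(0.001, 0.009, by = 0.001)  # distinct magnitudes
  b2 <- a + d
  p2 <- wilcoxon_compare(a, b2)
  r <- rank(abs(b2 - a))
  W_obs <- sum(r[(b2 - a) > 0])                  # all positive here
  signs <- expand.grid(rep(list(c(0, 1)), 9))
  W_all <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  p_exact <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
  expect_equal(p2, p_exact, tolerance = 1e-12)
  expect_lt(p, 0.05)                # constant +10 shift: clearly significant

  # symmetry of the two-sided test
  expect_equal(wilcoxon_compare(b2, a), p2, tolerance = 1e-12)
  expect_warning(pz <- wilcoxon_compare(a, a), "zero")
  expect_equal(pz, 1)
  expect_error(wilcoxon_compare(1:4, 2:5), "5 pairs")
})

test_that("the protocol runner never leaks test trials into training", {
  # leakage guard: the runner asserts disjoint indices and the augmented
  # training set is built from the train split only; a tampered split
  # (test-tagged train data) is refused by the augmenter
  x <- make_epochs(n = 30, C = 2, T = 40, n_cls = 2, seed = 31)
  proto <- train_protocol(n_repeats = 2, max_epochs = 1, seed = 4,
                          augment = list(n_segments = 4, multiplier = 1))
  sp <- split_within_session(x, proto, 1)
  expect_length(intersect(sp$indices$train, sp$indices$test), 0)
  expect_error(build_augmented_train_set(sp$test, n_segments = 4), "leakage")
})
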