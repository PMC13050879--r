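test_that("sliding-window partition counts and indexes blocks correctly", {
  p <- block_partition(13, 4, 1)
  expect_equal(p$m, 10L)                       # the encoder's working regime
  expect_equal(p$index_map[1, ], 0:3)
  expect_equal(p$index_map[10, ], 9:12)

  tiling <- block_partition(12, 4, 4)
  expect_equal(tiling$m, 3L)
  expect_equal(sort(as.vector(tiling$index_map)), 0:11)  # disjoint cover

  # oracle: enumerate every valid window start
  for (case in list(c(13, 5, 3), c(20, 7, 2), c(9, 9, 1), c(10, 3, 4))) {
    n <- case[1]; s <- case[2]; d <- case[3]
    starts <- seq(0, n - s, by = d)
    p <- block_partition(n, s, d)
    expect_equal(p$m, length(starts))
    expect_equal(p$index_map[, 1], starts)
    expect_true(all(p$index_map < n))
    expect_equal(length(p$index_map), p$m * s)
  }
  expect_error(block_partition(5, 6, 1), "window")
  expect_error(block_partition(5, 2, 0), "stride")
})

test_that("block key/value averaging matches a loop-based mean oracle", {
  set.seed(21)
  part <- block_partition(11, 3, 2)
  K <- matrix(rnorm(11 * 4), 11, 4)
  V <- matrix(rnorm(11 * 4), 11, 4)
  agg <- aggregate_block_kv(K, V, part)
  for (j in seq_len(part$m)) {
    idx <- part$index_map[j, ] + 1
    expect_equal(agg$K_avg[j, ], colMeans(K[idx, , drop = FALSE]))
    expect_equal(agg$V_avg[j, ], colMeans(V[idx, , drop = FALSE]))
  }
  # constant block collapses to the shared token
  Kc <- matrix(1:4, 11, 4, byrow = TRUE)
  expect_equal(aggregate_block_kv(Kc, Kc, part)$K_avg[1, ], as.numeric(1:4))
  # singleton blocks are the identity
  p1 <- block_partition(6, 1, 1)
  expect_equal(aggregate_block_kv(K[1:6, ], V[1:6, ], p1)$K_avg, K[1:6, ])
})

test_that("aggregation attention with singleton blocks equals dense attention", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:32, 1)
    dk <- sample(2:16, 1)
    Q <- matrix(rnorm(n * dk), n, dk)
    K <- matrix(rnorm(n * dk), n, dk)
    V <- matrix(rnorm(n * dk), n, dk)
    part <- block_partition(n, 1, 1)
    agg <- aggregate_block_kv(K, V, part)
    out <- aggregation_attention(Q, agg$K_avg, agg$V_avg, dk)
    expect_lt(max(abs(out$output - dense_attention(Q, K, V))), 1e-5)
    expect_equal(dim(out$S_m), c(n, n))   # m == n here, never more
  }
})

test_that("aggregation attention is convex in the block values", {
  set.seed(5)
  part <- block_partition(12, 3, 3)
  K <- matrix(rnorm(12 * 4), 12, 4)
  v <- rnorm(4)
  V_avg <- matrix(v, part$m, 4, byrow = TRUE)   # all blocks share one value
  out <- aggregation_attention(matrix(rnorm(12 * 4), 12, 4),
                               aggregate_block_kv(K, K, part)$K_avg,
                               V_avg, 4)
  expect_equal(out$output, matrix(v, 12, 4, byrow = TRUE), tolerance = 1e-9)

  # single block: softmax over one logit is 1
  p1 <- block_partition(6, 6, 1)
  a1 <- aggregate_block_kv(K[1:6, ], K[1:6, ], p1)
  o1 <- aggregation_attention(matrix(rnorm(6 * 4), 6, 4), a1$K_avg,
                              a1$V_avg, 4)
  expect_equal(o1$output, matrix(a1$V_avg[1, ], 6, 4, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("top-k masks keep exactly k blocks with stable tie-breaks", {
  m1 <- topk_block_mask(matrix(c(0.5, 2, 1), 1), 1)
  expect_equal(which(is.finite(m1)), 2L)

  S <- matrix(rnorm(30), 5, 6)
  expect_true(all(is.finite(topk_block_mask(S, 6))))  # k = m: all-pass
  expect_error(topk_block_mask(S, 7), "blocks")

  # ties at the k-th score resolve to the lowest block index; verify against
  # a stable-sort oracle on heavily tied scores
  set.seed(31)
  for (rep in 1:50) {
    St <- matrix(sample(1:3, 24, replace = TRUE), 4, 6)
    k <- sample(1:6, 1)
    mask <- topk_block_mask(St, k)
    for (q in 1:4) {
      keep <- which(is.finite(mask[q, ]))
      oracle <- sort(order(-St[q, ], seq_len(6))[seq_len(k)])
      expect_identical(keep, oracle)
      expect_length(keep, k)
    }
  }
})

test_that("top attention over all disjoint blocks equals dense attention", {
  for (seed in 1:100) {
    set.seed(100 + seed)
    s <- sample(2:4, 1)
    m <- sample(2:8, 1)
    n <- s * m
    dk <- sample(2:16, 1)
    Q <- matrix(rnorm(n * dk), n, dk)
    K <- matrix(rnorm(n * dk), n, dk)
    V <- matrix(rnorm(n * dk), n, dk)
    part <- block_partition(n, s, s)            # disjoint tiling
    mask <- matrix(1, n, part$m)                # k = m
    out <- top_attention(Q, K, V, part, mask, dk)
    expect_lt(max(abs(out - dense_attention(Q, K, V))), 1e-5)
  }
})

test_that("top attention duplicates shared tokens of overlapping blocks", {
  # explicit token-expansion oracle for d < s with every block kept
  set.seed(77)
  n <- 9; s <- 4; d <- 2; dk <- 3
  part <- block_partition(n, s, d)
  Q <- matrix(rnorm(n * dk), n, dk)
  K <- matrix(rnorm(n * dk), n, dk)
  V <- matrix(rnorm(n * dk), n, dk)
  mask <- matrix(1, n, part$m)
  out <- top_attention(Q, K, V, part, mask, dk)
  expanded <- as.vector(t(part$index_map)) + 1  # duplicates kept per block
  oracle <- dense_attention(Q, K[expanded, ], V[expanded, ])
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("a single selected block of constant values returns that value", {
  part <- block_partition(8, 2, 2)
  K <- matrix(rnorm(8 * 2), 8, 2)
  V <- matrix(5, 8, 2)
  V[3:4, ] <- -1                                # block 2's tokens
  mask <- matrix(-Inf, 8, part$m)
  mask[, 2] <- 1                                # every query keeps block 2
  out <- top_attention(matrix(rnorm(16), 8, 2), K, V, part, mask, 2)
  expect_equal(out, matrix(-1, 8, 2), tolerance = 1e-12)
})

test_that("block order in the partition does not affect the outputs", {
  set.seed(13)
  n <- 12; s <- 3; d <- 2; dk <- 4
  part <- block_partition(n, s, d)
  Q <- matrix(rnorm(n * dk), n, dk)
  K <- matrix(rnorm(n * dk), n, dk)
  V <- matrix(rnorm(n * dk), n, dk)
  perm <- sample(part$m)
  part2 <- part
  part2$index_map <- part$index_map[perm, ]

  a1 <- aggregate_block_kv(K, V, part)
  a2 <- aggregate_block_kv(K, V, part2)
  expect_equal(a2$K_avg, a1$K_avg[perm, ])

  o1 <- aggregation_attention(Q, a1$K_avg, a1$V_avg, dk)
  o2 <- aggregation_attention(Q, a2$K_avg, a2$V_avg, dk)
  expect_equal(o2$output, o1$output, tolerance = 1e-12)

  mask1 <- matrix(1, n, part$m)
  expect_equal(top_attention(Q, K, V, part2, mask1, dk),
               top_attention(Q, K, V, part, mask1, dk), tolerance = 1e-12)
})

test_that("score matrices stay at the sparse sizes, never n x n", {
  n <- 24; s <- 4; d <- 2
  part <- block_partition(n, s, d)
  expect_lt(part$m, n)
  K <- matrix(rnorm(n * 4), n, 4)
  agg <- aggregate_block_kv(K, K, part)
  out <- aggregation_attention(matrix(rnorm(n * 4), n, 4), agg$K_avg,
                               agg$V_avg, 4)
  expect_equal(dim(out$S_m), c(n, part$m))      # O(n m), not O(n^2)
  k <- auto_top_k(part$m)
  expect_lte(k, part$m %/% 2)                   # below half the blocks
  mask <- topk_block_mask(out$S_m, k)
  sel <- mieeg:::selected_token_index(part, mask)
  expect_equal(dim(sel), c(n, k * s))           # O(n k s) restored tokens
})

test_that("auto top-k keeps at least one block and stays below m/2", {
  for (m in 1:40) {
    k <- auto_top_k(m)
    expect_gte(k, 1L)
    if (m >= 3) expect_lte(k, m %/% 2)
  }
})
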