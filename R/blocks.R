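# Sparse information-aggregation attention primitives.
#
# A token sequence of length n is cut into m = floor((n - s)/d) + 1 sliding
# blocks of s consecutive tokens starting every d tokens (overlapping when
# d < s). Keys/values are block-averaged for a coarse "aggregation" pass
# whose score matrix is n x m instead of n x n; the same scores then rank
# blocks per query and only the tokens of the top-k blocks are restored for
# a fine-grained "top" pass over n x (k*s) scores. The dense n x n score
# matrix is never formed.

#' Sliding-window block partition of a token sequence
#'
#' @param n sequence length (tokens).
#' @param s window (block) length, `1 <= s <= n`.
#' @param d stride between block starts, `>= 1`.
#' @return an object of class `block_partition` with fields `n`, `s`, `d`,
#'   `m` (block count `floor((n - s)/d) + 1`) and `index_map`, an `m x s`
#'   integer matrix whose row j holds the 0-based token indices
#'   `(j-1)*d + (0:(s-1))` of block j.
#' @examples
#' block_partition(13, 4, 1)$m  # 10 blocks
#' @export
block_partition <- function(n, s, d) {
  n <- as.integer(n); s <- as.integer(s); d <- as.integer(d)
  if (s < 1L || s > n) stop("window s must satisfy 1 <= s <= n", call. = FALSE)
  if (d < 1L) stop("stride d must be >= 1", call. = FALSE)
  m <- (n - s) %/% d + 1L
  index_map <- outer((seq_len(m) - 1L) * d, 0L:(s - 1L), `+`)
  structure(list(n = n, s = s, d = d, m = m, index_map = index_map),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> n=%d tokens, window s=%d, stride d=%d -> m=%d blocks (%s)\n",
              x$n, x$s, x$d, x$m,
              if (x$d >= x$s) "disjoint" else "overlapping"))
  invisible(x)
}

#' Block-average keys and values
#'
#' Row j of each output is the arithmetic mean of the key (value) rows of
#' the tokens in block j — the coarse, global representation each query
#' scores against.
#'
#' @param K,V `n x d_k` matrices of per-token keys and values.
#' @param part a [block_partition()] with `part$n == nrow(K)`.
#' @return list with `K_avg` and `V_avg`, both `m x d_k`.
#' @export
aggregate_block_kv <- function(K, V, part) {
  if (nrow(K) != part$n || nrow(V) != part$n)
    stop("K/V rows must equal partition length n", call. = FALSE)
  pool <- block_pool_matrix(part)
  list(K_avg = pool %*% K, V_avg = pool %*% V)
}

# m x n averaging operator: row j has 1/s at the token positions of block j.
block_pool_matrix <- function(part) {
  pool <- matrix(0, part$m, part$n)
  pool[cbind(rep(seq_len(part$m), part$s),
             as.vector(part$index_map) + 1L)] <- 1 / part$s
  pool
}

#' Aggregation attention over block-averaged keys/values
#'
#' Per-token queries attend to the m block means:
#' `softmax(Q K_avg' / sqrt(d_k)) V_avg`. The pre-softmax score matrix
#' (`n x m`) is returned as well, because top-k block selection reuses it at
#' no extra cost.
#'
#' @param Q `n x d_k` query matrix.
#' @param K_avg,V_avg `m x d_k` block-averaged keys/values.
#' @param d_k key dimension used in the `1/sqrt(d_k)` scaling (defaults to
#'   `ncol(Q)`).
#' @return list with `output` (`n x d_k`) and `S_m` (`n x m`, pre-softmax).
#' @export
aggregation_attention <- function(Q, K_avg, V_avg, d_k = ncol(Q)) {
  S_m <- tcrossprod(Q, K_avg) / sqrt(d_k)
  list(output = softmax_rows(S_m) %*% V_avg, S_m = S_m)
}

#' Per-query top-k block selection mask
#'
#' For every query row of the aggregation score matrix, keeps exactly the k
#' highest-scoring blocks; all other blocks get a `-Inf` logit. Ties at the
#' k-th score resolve to the lowest block index (deterministic).
#'
#' @param S_m `n x m` pre-softmax aggregation scores.
#' @param k blocks kept per query, `1 <= k <= m`.
#' @return `n x m` matrix with 1 at selected blocks and `-Inf` elsewhere.
#' @export
topk_block_mask <- function(S_m, k) {
  m <- ncol(S_m)
  if (k < 1 || k > m) stop("need 1 <= k <= m blocks", call. = FALSE)
  mask <- matrix(-Inf, nrow(S_m), m)
  for (q in seq_len(nrow(S_m))) {
    # order() is a stable sort: equal scores keep ascending block index
    sel <- order(-S_m[q, ])[seq_len(k)]
    mask[q, sel] <- 1
  }
  mask
}

#' Fine-grained attention over the tokens of the selected blocks
#'
#' The s original tokens of each query's k selected blocks are restored
#' (tokens shared by overlapping blocks are kept once per block, so each
#' query attends over exactly `k*s` token slots) and a fresh softmax
#' attention is computed over them: `softmax(Q K_top' / sqrt(d_k)) V_top`.
#'
#' @param Q,K,V `n x d_k` per-token matrices.
#' @param part a [block_partition()] for the sequence.
#' @param mask selection mask from [topk_block_mask()].
#' @param d_k key dimension for score scaling (defaults to `ncol(Q)`).
#' @return `n x d_k` attention output.
#' @export
top_attention <- function(Q, K, V, part, mask, d_k = ncol(Q)) {
  sel <- selected_token_index(part, mask)       # n x (k*s), 1-based
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (q in seq_len(n)) {
    idx <- sel[q, ]
    sc <- (K[idx, , drop = FALSE] %*% Q[q, ]) / sqrt(d_k)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    out[q, ] <- crossprod(V[idx, , drop = FALSE], w)
  }
  out
}

# n x (k*s) matrix of 1-based token indices restored for each query.
selected_token_index <- function(part, mask) {
  k <- sum(is.finite(mask[1L, ]))
  if (any(rowSums(is.finite(mask)) != k))
    stop("mask must select the same number of blocks per query", call. = FALSE)
  n <- nrow(mask)
  sel <- matrix(0L, n, k * part$s)
  for (q in seq_len(n)) {
    blocks <- which(is.finite(mask[q, ]))
    sel[q, ] <- as.vector(t(part$index_map[blocks, , drop = FALSE])) + 1L
  }
  sel
}

#' Number of blocks kept by the default "auto" top-k rule
#'
#' Keeps `max(1, floor(m/3))` blocks — comfortably below half the block
#' count, so the top pass stays genuinely sparse even for short sequences.
#'
#' @param m total number of blocks.
#' @return integer k.
#' @export
auto_top_k <- function(m) max(1L, m %/% 3L)
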