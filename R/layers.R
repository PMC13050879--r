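# Minimal neural-network primitives (forward + hand-derived backward) on
# plain R matrices/arrays, BLAS-backed via im2col matmuls. Shapes follow
# the internal batch layout: time-major arrays [T, B, ...] and flattened
# matrices whose rows are ordered (time fastest, then trial).

EPS_BN <- 1e-5

# Fast column-wise broadcast ops (x: [N, F], v: length-F vector). Equivalent
# to sweep(x, 2, v, op) without its generic-dispatch and aperm overhead.
col_add <- function(x, v) x + rep(v, each = nrow(x))
col_sub <- function(x, v) x - rep(v, each = nrow(x))
col_mult <- function(x, v) x * rep(v, each = nrow(x))

# ---- 1-d "same" convolution over the leading (time) axis -------------------

# FFT-based temporal convolution of a single-map input. X: [T, B, C]
# (time-major), kernels W [F1, k] (k odd), same zero padding. Output is the
# [T*B*C, F1] matrix of filtered traces (rows ordered t, b, c). Large EEG
# kernels (~fs/2 taps) make frequency-domain convolution much cheaper than
# im2col here; N is padded to a 2-3-5-smooth length so circular convolution
# never aliases the linear one.
conv_temporal_fw <- function(X, W, b) {
  d <- dim(X); T <- d[1L]; R <- d[2L] * d[3L]
  F1 <- nrow(W); k <- ncol(W)
  pad <- (k - 1L) %/% 2L
  N <- stats::nextn(T + k - 1L, factors = c(2, 3, 5))
  xp <- matrix(0, N, R)
  xp[seq_len(T), ] <- X
  XF <- stats::mvfft(xp)
  wp <- matrix(0, N, F1)
  wp[seq_len(k), ] <- t(W[, k:1, drop = FALSE])  # reversed taps: conv == corr
  WF <- stats::mvfft(wp)
  out <- matrix(0, T * R, F1)
  sel <- (k - pad):(T + k - 1L - pad)
  for (f in seq_len(F1)) {
    cf <- Re(stats::mvfft(XF * WF[, f], inverse = TRUE)) / N
    out[, f] <- cf[sel, ]
  }
  out <- col_add(out, b)
  list(out = out, cache = list(XF = XF, dims = d, N = N, k = k, pad = pad))
}

# dout: [T*B*C, F1]; returns kernel/bias gradients (input gradient is never
# needed: this is the first layer).
conv_temporal_bw <- function(dout, W, cache) {
  d <- cache$dims; T <- d[1L]; R <- d[2L] * d[3L]
  F1 <- nrow(W); k <- cache$k; pad <- cache$pad; N <- cache$N
  db <- colSums(dout)
  dW <- matrix(0, F1, k)
  ones <- rep(1, R)
  lag_idx <- (((0:(k - 1L)) - pad) %% N) + 1L
  dp <- matrix(0, N, R)
  for (f in seq_len(F1)) {
    dp[seq_len(T), ] <- dout[, f]
    DF <- stats::mvfft(dp)
    G <- (Conj(DF) * cache$XF) %*% ones
    g <- Re(stats::fft(G[, 1L], inverse = TRUE)) / N
    dW[f, ] <- g[lag_idx]
  }
  list(dW = dW, db = db)
}

# Multi-map temporal convolution: A [L, B, F_in] -> out [F_out, L*B].
# Weights W [F_out, F_in * w] (tap-major blocks of F_in), bias b.
conv_multimap_fw <- function(A, W, b, w) {
  d <- dim(A); L <- d[1L]; B <- d[2L]; Fi <- d[3L]
  pad <- (w - 1L) %/% 2L
  apad <- array(0, c(L + w - 1L, B, Fi))
  apad[(pad + 1L):(pad + L), , ] <- A
  cols <- matrix(0, Fi * w, L * B)
  for (tau in seq_len(w)) {
    sl <- apad[tau:(tau + L - 1L), , , drop = FALSE]   # [L, B, Fi]
    cols[((tau - 1L) * Fi + 1L):(tau * Fi), ] <- t(matrix(sl, L * B, Fi))
  }
  list(out = W %*% cols + b, cache = list(cols = cols, d = d, w = w))
}

conv_multimap_bw <- function(dout, W, cache) {
  d <- cache$d; L <- d[1L]; B <- d[2L]; Fi <- d[3L]; w <- cache$w
  pad <- (w - 1L) %/% 2L
  db <- rowSums(dout)
  dW <- tcrossprod(dout, cache$cols)
  dcols <- crossprod(W, dout)                  # [Fi*w, L*B]
  dapad <- array(0, c(L + w - 1L, B, Fi))
  for (tau in seq_len(w)) {
    blk <- t(dcols[((tau - 1L) * Fi + 1L):(tau * Fi), , drop = FALSE])
    dapad[tau:(tau + L - 1L), , ] <- dapad[tau:(tau + L - 1L), , ] +
      array(blk, c(L, B, Fi))
  }
  list(dA = dapad[(pad + 1L):(pad + L), , , drop = FALSE], dW = dW, db = db)
}

# ---- batch normalization (per feature column over all rows) ----------------

batchnorm_fw <- function(x, gamma, beta, state, train, momentum = 0.1) {
  if (train) {
    mu <- colMeans(x)
    xc <- col_sub(x, mu)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + EPS_BN)
    xhat <- col_mult(xc, ivar)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
    cache <- list(xhat = xhat, ivar = ivar)
  } else {
    xhat <- col_mult(col_sub(x, state$mean), 1 / sqrt(state$var + EPS_BN))
    cache <- NULL
  }
  y <- col_add(col_mult(xhat, gamma), beta)
  list(out = y, cache = cache, state = state)
}

batchnorm_bw <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  N <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- col_mult(dy, gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- col_sub(dxhat, s1 / N) - col_mult(xhat, s2 / N)
  dx <- col_mult(dx, cache$ivar)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- layer normalization (per row over feature columns) --------------------

layernorm_fw <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + EPS_BN)
  xhat <- xc * ivar
  y <- col_add(col_mult(xhat, gamma), beta)
  list(out = y, cache = list(xhat = xhat, ivar = ivar))
}

layernorm_bw <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  Fd <- ncol(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- col_mult(dy, gamma)
  s1 <- rowMeans(dxhat)
  s2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - s1 - xhat * s2) * cache$ivar
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling over the leading (time) axis ----------------------------------

# x: array [T, ...]; non-overlapping mean pool of width p over dim 1,
# trailing remainder samples dropped (floor semantics).
pool_time_fw <- function(x, p) {
  d <- dim(x)
  L <- d[1L] %/% p
  xr <- array(x[seq_len(L * p), , , drop = FALSE], c(p, L, d[-1L]))
  out <- array(colMeans(xr), c(L, d[-1L]))
  list(out = out, cache = list(d = d, p = p, L = L))
}

pool_time_bw <- function(dout, cache) {
  d <- cache$d; p <- cache$p; L <- cache$L
  dx <- array(0, d)
  g <- array(rep(as.vector(dout) / p, each = p), c(p * L, d[-1L]))
  dx[seq_len(p * L), , ] <- g
  dx
}

# ---- dropout (inverted scaling) --------------------------------------------

dropout_fw <- function(x, p, train, rng) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- (rng$unif(length(x)) >= p) / (1 - p)
  mask <- array(mask, dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}

dropout_bw <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- dense -----------------------------------------------------------------

dense_fw <- function(x, W, b) {
  list(out = col_add(x %*% W, b), cache = x)
}

dense_bw <- function(dout, W, cache) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache, dout),
       db = colSums(dout))
}
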