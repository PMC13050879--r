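# Network assembly: multi-scale spatio-temporal convolutional front end,
# cross-branch additive recalibration with CBAM, position-aware enhancement,
# sparse-attention encoder, dense classifier. Forward and backward are
# hand-derived; the batch layout is time-major throughout (see layers.R).

#' Sparse-attention encoder configuration
#'
#' @param d_model embedding width per token (equals the spatial filter count
#'   `F2` of the front end).
#' @param n_heads attention heads `h`; must divide `d_model`.
#' @param n_layers stacked encoder layers `N`.
#' @param window sliding-window block length `s` (tokens).
#' @param stride block stride `d`; overlapping blocks when `stride < window`.
#' @param top_k blocks restored per query, or `"auto"` for
#'   `max(1, floor(m/3))` — below half the block count so the top pass stays
#'   sparse.
#' @param ffn_expansion width multiplier of an optional position-wise
#'   feed-forward sublayer; `0` (default) omits it, leaving lightweight
#'   attention-only layers.
#' @param dropout dropout rate on each layer's attention projection.
#' @return a `sat_config` list.
#' @export
sat_config <- function(d_model = 32, n_heads = 4, n_layers = 6, window = 4,
                       stride = 1, top_k = "auto", ffn_expansion = 0,
                       dropout = 0.3) {
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), window = as.integer(window),
                 stride = as.integer(stride), top_k = top_k,
                 ffn_expansion = ffn_expansion, dropout = dropout),
            class = "sat_config")
}

nearest_odd <- function(x) as.integer(2 * round((x - 1) / 2) + 1)

#' Model architecture configuration
#'
#' Collects every architecture hyperparameter: input geometry, the three
#' temporal kernel scales (half/quarter/eighth of the sampling rate, rounded
#' to odd lengths for symmetric same-padding), filter counts, pooling
#' widths, CBAM reduction, classifier shape and the sparse-attention
#' settings. Derived token counts are computed with floor division, e.g.
#' `T = 1000, pool1 = 75` gives 13 tokens into the encoder.
#'
#' @param C number of EEG channels.
#' @param T samples per trial.
#' @param n_classes number of motor-imagery classes.
#' @param fs sampling rate in Hz (drives the temporal kernel sizes).
#' @param F1 temporal filters per branch.
#' @param F2 spatial filters (token embedding width).
#' @param temporal_kernels optional integer vector of 3 odd kernel lengths;
#'   default `nearest_odd(fs / c(2, 4, 8))`.
#' @param pool1 front-end average-pooling width (samples).
#' @param pae_kernels the two parallel enhancement kernel widths.
#' @param pool2 enhancement-stage average-pooling width.
#' @param dropout dropout rate used at every dropout site.
#' @param cbam_reduction channel-attention bottleneck ratio `r`.
#' @param classifier_hidden hidden width of the classifier; `0` (default)
#'   uses a single dense softmax layer, `> 0` inserts a hidden ELU layer
#'   with dropout.
#' @param spatial_mode `"depthwise"` (default; `F2` kernels of size `(C,1)`,
#'   `F2/F1` per temporal map) or `"standard"` (`F2` kernels spanning all
#'   `F1` maps).
#' @param sat a [sat_config()]; its `d_model` must equal `F2`.
#' @return a `model_config` list with derived fields `L1` (post-front-end
#'   tokens), `L2` (encoder token count) and `partition`.
#' @export
model_config <- function(C, T, n_classes, fs = 250, F1 = 16, F2 = 32,
                         temporal_kernels = NULL, pool1 = 75,
                         pae_kernels = c(3, 7), pool2 = 3, dropout = 0.3,
                         cbam_reduction = 8, classifier_hidden = 0,
                         spatial_mode = c("depthwise", "standard"),
                         sat = NULL) {
  spatial_mode <- match.arg(spatial_mode)
  if (T < pool1) stop("T must be at least pool1 samples", call. = FALSE)
  if (is.null(temporal_kernels))
    temporal_kernels <- nearest_odd(fs / c(2, 4, 8))
  if (length(temporal_kernels) != 3L || any(temporal_kernels %% 2 == 0))
    stop("temporal_kernels must be 3 odd integers", call. = FALSE)
  if (F2 %% F1 != 0 && spatial_mode == "depthwise")
    stop("depthwise spatial convolution needs F2 divisible by F1", call. = FALSE)
  if (is.null(sat)) sat <- sat_config(d_model = F2)
  if (sat$d_model != F2)
    stop("sat$d_model must equal F2", call. = FALSE)
  L1 <- T %/% pool1
  Lc <- 3L * L1
  if (Lc < pool2) stop("3*floor(T/pool1) must be at least pool2", call. = FALSE)
  L2 <- Lc %/% pool2
  if (sat$window > L2)
    stop("sat window exceeds encoder token count", call. = FALSE)
  part <- block_partition(L2, sat$window, sat$stride)
  k <- if (identical(sat$top_k, "auto")) auto_top_k(part$m)
       else as.integer(sat$top_k)
  if (k < 1 || k > part$m) stop("top_k must lie in [1, m]", call. = FALSE)
  structure(list(C = as.integer(C), T = as.integer(T), fs = fs,
                 n_classes = as.integer(n_classes), F1 = as.integer(F1),
                 F2 = as.integer(F2),
                 temporal_kernels = as.integer(temporal_kernels),
                 pool1 = as.integer(pool1),
                 pae_kernels = as.integer(pae_kernels),
                 pool2 = as.integer(pool2), dropout = dropout,
                 cbam_reduction = as.integer(cbam_reduction),
                 classifier_hidden = as.integer(classifier_hidden),
                 spatial_mode = spatial_mode, sat = sat,
                 L1 = L1, L2 = L2, partition = part, top_k = k),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %d ch x %d samples @ %g Hz -> %d classes\n",
              x$C, x$T, x$fs, x$n_classes))
  cat(sprintf("  front end: F1=%d kernels (%s), F2=%d (%s spatial), pool %d -> %d tokens\n",
              x$F1, paste(x$temporal_kernels, collapse = "/"), x$F2,
              x$spatial_mode, x$pool1, x$L1))
  cat(sprintf("  enhancement: kernels (%s), pool %d -> %d tokens\n",
              paste(x$pae_kernels, collapse = ","), x$pool2, x$L2))
  cat(sprintf("  encoder: N=%d layers, h=%d heads, window s=%d stride d=%d, m=%d blocks, top-k=%d\n",
              x$sat$n_layers, x$sat$n_heads, x$sat$window, x$sat$stride,
              x$partition$m, x$top_k))
  invisible(x)
}

# ---- parameter initialization ----------------------------------------------

init_params <- function(cfg, seed = 1) {
  rng <- local_rng(derive_seed(seed, "init"))
  he <- function(nr, nc, fan) matrix(rng$norm(nr * nc) * sqrt(2 / fan), nr, nc)
  F1 <- cfg$F1; F2 <- cfg$F2; r <- max(1L, F2 %/% cfg$cbam_reduction)
  branches <- lapply(cfg$temporal_kernels, function(k) {
    sW <- if (cfg$spatial_mode == "depthwise") he(F2, cfg$C, cfg$C)
          else he(F2, F1 * cfg$C, F1 * cfg$C)
    list(
      tconv = list(W = he(F1, k, k), b = numeric(F1)),
      sconv = list(W = sW, b = numeric(F2)),
      bn = list(gamma = rep(1, F2), beta = numeric(F2)),
      cbam = list(W1 = he(F2, r, F2), b1 = numeric(r),
                  W2 = he(r, F2, r), b2 = numeric(F2),
                  Wsp = he(2L, 3L, 6L), bsp = 0))
  })
  w1 <- cfg$pae_kernels[1L]; w2 <- cfg$pae_kernels[2L]
  pae <- list(
    conv1 = list(W = he(F2, F2 * w1, F2 * w1), b = numeric(F2)),
    conv2 = list(W = he(F2, F2 * w2, F2 * w2), b = numeric(F2)),
    bn1 = list(gamma = rep(1, F2), beta = numeric(F2)),
    bn2 = list(gamma = rep(1, F2), beta = numeric(F2)),
    pos = matrix(rng$norm(cfg$L2 * F2), cfg$L2, F2))  # standard-normal init
  sat <- lapply(seq_len(cfg$sat$n_layers), function(l) {
    p <- list(ln1 = list(gamma = rep(1, F2), beta = numeric(F2)),
              Wq = he(F2, F2, 2 * F2), bq = numeric(F2),
              Wk = he(F2, F2, 2 * F2), bk = numeric(F2),
              Wv = he(F2, F2, 2 * F2), bv = numeric(F2),
              Wo = he(F2, F2, 2 * F2), bo = numeric(F2),
              ln2 = list(gamma = rep(1, F2), beta = numeric(F2)))
    if (cfg$sat$ffn_expansion > 0) {
      dff <- max(1L, as.integer(round(F2 * cfg$sat$ffn_expansion)))
      p$ffn <- list(W1 = he(F2, dff, F2), b1 = numeric(dff),
                    W2 = he(dff, F2, dff), b2 = numeric(F2))
    }
    p
  })
  n_flat <- cfg$L2 * F2
  clf <- if (cfg$classifier_hidden > 0) {
    list(W1 = he(n_flat, cfg$classifier_hidden, n_flat),
         b1 = numeric(cfg$classifier_hidden),
         W2 = he(cfg$classifier_hidden, cfg$n_classes, cfg$classifier_hidden),
         b2 = numeric(cfg$n_classes))
  } else {
    list(W = he(n_flat, cfg$n_classes, n_flat), b = numeric(cfg$n_classes))
  }
  list(branches = branches, pae = pae, sat = sat, clf = clf)
}

# Non-learnable batch-norm running statistics.
init_state <- function(cfg) {
  bn0 <- function() list(mean = numeric(cfg$F2), var = rep(1, cfg$F2))
  list(branches = lapply(1:3, function(i) list(bn = bn0())),
       pae = list(bn1 = bn0(), bn2 = bn0()))
}

# ---- parameter flattening (for the optimizer and counting) -----------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

#' Count the learnable parameters of a model configuration
#'
#' Sums every trainable weight, bias, normalization affine and the
#' positional matrix. The `breakdown` attribute gives per-module subtotals.
#'
#' @param cfg a [model_config()] (or a fitted `mi_decoder`).
#' @return integer total; `attr(, "breakdown")` is a named integer vector
#'   over modules (`stconv`, `afr_cbam`, `pae`, `sat`, `classifier`).
#' @examples
#' cfg <- model_config(C = 3, T = 1000, n_classes = 2)
#' count_parameters(cfg)
#' @export
count_parameters <- function(cfg) {
  if (inherits(cfg, "mi_decoder")) cfg <- cfg$config
  p <- init_params(cfg, seed = 1)
  n_of <- function(x) length(flatten_params(x))
  breakdown <- c(
    stconv = sum(vapply(p$branches, function(b)
      n_of(b[c("tconv", "sconv", "bn")]), 0)),
    afr_cbam = sum(vapply(p$branches, function(b) n_of(b$cbam), 0)),
    pae = n_of(p$pae),
    sat = n_of(p$sat),
    classifier = n_of(p$clf))
  structure(as.integer(sum(breakdown)),
            breakdown = as.integer(breakdown) |>
              stats::setNames(names(breakdown)))
}

# ---- forward pass ----------------------------------------------------------

# X: array [T, B, C] (time-major). Returns probs [B, n_classes] and (train)
# a cache for the backward pass. `state` holds BN running stats and is
# updated in train mode. rng drives dropout.
apc_forward <- function(params, state, X, cfg, train = FALSE, rng = NULL) {
  d <- dim(X); T <- d[1L]; B <- d[2L]; C <- d[3L]
  stopifnot(T == cfg$T, C == cfg$C)
  F1 <- cfg$F1; F2 <- cfg$F2; L1 <- cfg$L1; L2 <- cfg$L2
  D <- F2 %/% F1
  cache <- list(branches = vector("list", 3L), B = B)

  branch_out <- vector("list", 3L)
  for (i in 1:3) {
    pb <- params$branches[[i]]
    bc <- list()
    tc <- conv_temporal_fw(X, pb$tconv$W, pb$tconv$b)
    bc$tconv <- tc$cache
    bc$t_out <- tc$out                           # [T*B*C, F1], rows (t, b, c)
    if (cfg$spatial_mode == "depthwise") {
      Z2 <- matrix(0, T * B, F2)
      for (f1 in seq_len(F1)) {
        M <- matrix(tc$out[, f1], T * B, C)
        rows <- (f1 - 1L) * D + seq_len(D)
        Z2[, rows] <- M %*% t(pb$sconv$W[rows, , drop = FALSE])
      }
      Z2 <- col_add(Z2, pb$sconv$b)
    } else {
      Min <- matrix(aperm(array(tc$out, c(T * B, C, F1)), c(1L, 3L, 2L)),
                    T * B, F1 * C)
      bc$sp_in <- Min
      Z2 <- col_add(Min %*% t(pb$sconv$W), pb$sconv$b)
    }
    bn <- batchnorm_fw(Z2, pb$bn$gamma, pb$bn$beta,
                       state$branches[[i]]$bn, train)
    state$branches[[i]]$bn <- bn$state
    bc$bn <- bn$cache
    bc$pre_elu <- bn$out
    act <- elu(bn$out)
    pl <- pool_time_fw(array(act, c(T, B, F2)), cfg$pool1)
    bc$pool <- pl$cache
    dr <- dropout_fw(pl$out, cfg$dropout, train, rng)
    bc$drop <- dr$cache
    branch_out[[i]] <- matrix(dr$out, L1 * B, F2)
    cache$branches[[i]] <- bc
  }

  # AFR: additive cross-branch interaction, then per-branch CBAM
  S <- afr_interaction(branch_out)[[1L]]
  cbam_out <- vector("list", 3L)
  for (i in 1:3) {
    cb <- cbam_fw(S, params$branches[[i]]$cbam, L1, B, F2)
    cbam_out[[i]] <- cb$out
    cache$branches[[i]]$cbam <- cb$cache
  }

  # temporal concatenation of the three recalibrated branches
  Lc <- 3L * L1
  Cc <- array(0, c(Lc, B, F2))
  for (i in 1:3)
    Cc[((i - 1L) * L1 + 1L):(i * L1), , ] <- array(cbam_out[[i]],
                                                   c(L1, B, F2))

  # position-aware enhancement
  pp <- params$pae
  c1 <- conv_multimap_fw(Cc, pp$conv1$W, pp$conv1$b, cfg$pae_kernels[1L])
  c2 <- conv_multimap_fw(Cc, pp$conv2$W, pp$conv2$b, cfg$pae_kernels[2L])
  bn1 <- batchnorm_fw(t(c1$out), pp$bn1$gamma, pp$bn1$beta,
                      state$pae$bn1, train)
  bn2 <- batchnorm_fw(t(c2$out), pp$bn2$gamma, pp$bn2$beta,
                      state$pae$bn2, train)
  state$pae$bn1 <- bn1$state
  state$pae$bn2 <- bn2$state
  pre <- bn1$out + bn2$out                       # [Lc*B, F2]
  act <- elu(pre)
  pl <- pool_time_fw(array(act, c(Lc, B, F2)), cfg$pool2)
  dr <- dropout_fw(pl$out, cfg$dropout, train, rng)
  posB <- aperm(array(pp$pos, c(L2, F2, B)), c(1L, 3L, 2L))
  tokens <- dr$out + posB
  cache$pae <- list(c1 = c1$cache, c2 = c2$cache, bn1 = bn1$cache,
                    bn2 = bn2$cache, pre = pre, pool = pl$cache,
                    drop = dr$cache)

  # sparse-attention encoder
  Xf <- matrix(tokens, L2 * B, F2)
  cache$sat <- vector("list", cfg$sat$n_layers)
  for (l in seq_len(cfg$sat$n_layers)) {
    st <- sat_layer_fw(Xf, params$sat[[l]], cfg, B, train, rng)
    Xf <- st$out
    cache$sat[[l]] <- st$cache
  }

  # classifier
  arr <- array(Xf, c(L2, B, F2))
  Fl <- matrix(aperm(arr, c(2L, 1L, 3L)), B, L2 * F2)
  pc <- params$clf
  if (cfg$classifier_hidden > 0) {
    d1 <- dense_fw(Fl, pc$W1, pc$b1)
    h_pre <- d1$out
    h <- elu(h_pre)
    dh <- dropout_fw(h, cfg$dropout, train, rng)
    d2 <- dense_fw(dh$out, pc$W2, pc$b2)
    logits <- d2$out
    cache$clf <- list(Fl = Fl, h_pre = h_pre, hdrop = dh$cache,
                      hin = dh$out)
  } else {
    d1 <- dense_fw(Fl, pc$W, pc$b)
    logits <- d1$out
    cache$clf <- list(Fl = Fl)
  }
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, cache = if (train) cache else NULL,
       state = state)
}

# AFR interaction rule: each branch keeps its own features and adds those of
# the other branches, i.e. every interaction output is the branch sum;
# differentiation then comes from the per-branch CBAM parameters.
afr_interaction <- function(branches) {
  s <- Reduce(`+`, branches)
  lapply(branches, function(b) s)
}

# ---- CBAM forward / backward -----------------------------------------------

cbam_fw <- function(S, p, L, B, F2) {
  arr <- array(S, c(L, B, F2))
  Mt <- matrix(aperm(arr, c(2L, 3L, 1L)), B * F2, L)
  imt <- max.col(Mt, ties.method = "first")
  mx <- matrix(Mt[cbind(seq_len(B * F2), imt)], B, F2)
  amx <- matrix(imt, B, F2)                      # argmax time index
  mn <- colMeans(arr)                            # over time axis -> [B, F2]
  pre_mx <- col_add(mx %*% p$W1, p$b1)
  pre_mn <- col_add(mn %*% p$W1, p$b1)
  h_mx <- pmax(pre_mx, 0)
  h_mn <- pmax(pre_mn, 0)
  a <- col_add(h_mx %*% p$W2 + h_mn %*% p$W2, 2 * p$b2)
  wc <- sigmoid(a)
  wcexp <- wc[rep(seq_len(B), each = L), , drop = FALSE]
  Yc <- S * wcexp
  # spatial path: per-position max/mean over feature maps, width-3 conv
  imx <- max.col(Yc, ties.method = "first")
  mxs <- Yc[cbind(seq_len(L * B), imx)]
  mns <- rowMeans(Yc)
  M1 <- matrix(mxs, L, B)
  M2 <- matrix(mns, L, B)
  z <- matrix(p$bsp, L, B)
  for (tau in 1:3) {
    off <- tau - 2L
    sl <- shift_rows(M1, off)
    z <- z + p$Wsp[1L, tau] * sl + p$Wsp[2L, tau] * shift_rows(M2, off)
  }
  ws <- sigmoid(z)
  out <- Yc * as.vector(ws)
  list(out = out,
       cache = list(S = S, arr_dim = c(L, B, F2), mx = mx, amx = amx,
                    mn = mn, pre_mx = pre_mx, pre_mn = pre_mn,
                    h_mx = h_mx, h_mn = h_mn, wc = wc, wcexp = wcexp,
                    Yc = Yc, imx = imx, M1 = M1, M2 = M2, ws = ws))
}

shift_rows <- function(M, off) {
  L <- nrow(M)
  out <- matrix(0, L, ncol(M))
  if (off == 0L) return(M)
  if (off > 0L) out[seq_len(L - off), ] <- M[(off + 1L):L, , drop = FALSE]
  else out[(-off + 1L):L, ] <- M[seq_len(L + off), , drop = FALSE]
  out
}

cbam_bw <- function(dout, p, cc) {
  L <- cc$arr_dim[1L]; B <- cc$arr_dim[2L]; F2 <- cc$arr_dim[3L]
  ws_v <- as.vector(cc$ws)
  dYc <- dout * ws_v
  dws <- matrix(rowSums(dout * cc$Yc), L, B)
  dz <- dws * cc$ws * (1 - cc$ws)
  dWsp <- matrix(0, 2L, 3L)
  dM1 <- matrix(0, L, B)
  dM2 <- matrix(0, L, B)
  for (tau in 1:3) {
    off <- tau - 2L
    dWsp[1L, tau] <- sum(dz * shift_rows(cc$M1, off))
    dWsp[2L, tau] <- sum(dz * shift_rows(cc$M2, off))
    dM1 <- dM1 + p$Wsp[1L, tau] * shift_rows(dz, -off)
    dM2 <- dM2 + p$Wsp[2L, tau] * shift_rows(dz, -off)
  }
  dbsp <- sum(dz)
  # spatial max/mean pools
  dYc[cbind(seq_len(L * B), cc$imx)] <- dYc[cbind(seq_len(L * B), cc$imx)] +
    as.vector(dM1)
  dYc <- dYc + as.vector(dM2) / F2
  # channel gate
  dS <- dYc * cc$wcexp
  prod_ <- dYc * cc$S
  dwc <- colSums(array(prod_, c(L, B, F2)))      # [B, F2]
  da <- dwc * cc$wc * (1 - cc$wc)
  dW2 <- crossprod(cc$h_mx, da) + crossprod(cc$h_mn, da)
  db2 <- 2 * colSums(da)
  dh_mx <- tcrossprod(da, p$W2) * (cc$pre_mx > 0)
  dh_mn <- tcrossprod(da, p$W2) * (cc$pre_mn > 0)
  dW1 <- crossprod(cc$mx, dh_mx) + crossprod(cc$mn, dh_mn)
  db1 <- colSums(dh_mx) + colSums(dh_mn)
  dmx <- tcrossprod(dh_mx, p$W1)
  dmn <- tcrossprod(dh_mn, p$W1)
  # channel max: route to argmax time index; channel mean: spread /L
  rows <- as.vector(cc$amx) + (rep(seq_len(B), times = F2) - 1L) * L
  cols <- rep(seq_len(F2), each = B)
  idx <- cbind(rows, cols)
  dS[idx] <- dS[idx] + as.vector(dmx)
  dS <- dS + dmn[rep(seq_len(B), each = L), , drop = FALSE] / L
  list(dS = dS,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wsp = dWsp, bsp = dbsp))
}

# ---- sparse-attention encoder layer ----------------------------------------

sat_layer_fw <- function(Xf, p, cfg, B, train = FALSE, rng = NULL) {
  n <- cfg$L2; F2 <- cfg$F2
  nh <- cfg$sat$n_heads; dk <- F2 %/% nh
  part <- cfg$partition; k <- cfg$top_k; s <- part$s
  ks <- k * s
  pool <- block_pool_matrix(part)
  ln1 <- layernorm_fw(Xf, p$ln1$gamma, p$ln1$beta)
  Q <- col_add(ln1$out %*% p$Wq, p$bq)
  K <- col_add(ln1$out %*% p$Wk, p$bk)
  V <- col_add(ln1$out %*% p$Wv, p$bv)
  H <- matrix(0, n * B, F2)
  hcache <- vector("list", B * nh)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * n + seq_len(n)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      Qb <- Q[rows, cols, drop = FALSE]
      Kb <- K[rows, cols, drop = FALSE]
      Vb <- V[rows, cols, drop = FALSE]
      Kavg <- pool %*% Kb
      Vavg <- pool %*% Vb
      Sm <- tcrossprod(Qb, Kavg) / sqrt(dk)      # n x m, never n x n
      P1 <- softmax_rows(Sm)
      O1 <- P1 %*% Vavg
      idx <- matrix(0L, n, ks)
      for (q in seq_len(n)) {
        blocks <- order(-Sm[q, ])[seq_len(k)]    # stable: ties -> low index
        idx[q, ] <- as.vector(t(part$index_map[blocks, , drop = FALSE])) + 1L
      }
      flat <- as.vector(t(idx))
      sc <- matrix(rowSums(Kb[flat, , drop = FALSE] *
                             Qb[rep(seq_len(n), each = ks), , drop = FALSE]),
                   n, ks, byrow = TRUE) / sqrt(dk)
      P2 <- softmax_rows(sc)                     # n x (k*s), never n x n
      O2 <- matrix(0, n, dk)
      for (j in seq_len(ks))
        O2 <- O2 + P2[, j] * Vb[idx[, j], , drop = FALSE]
      H[rows, cols] <- O1 + O2
      hcache[[(b - 1L) * nh + h]] <- list(P1 = P1, P2 = P2, idx = idx)
    }
  }
  proj <- dense_fw(H, p$Wo, p$bo)
  dr <- dropout_fw(proj$out, cfg$sat$dropout, train, rng)
  Y <- Xf + dr$out
  ln2 <- layernorm_fw(Y, p$ln2$gamma, p$ln2$beta)
  cache <- list(ln1 = ln1$cache, ln1_out = ln1$out, Q = Q, K = K, V = V,
                H = H, drop = dr$cache, Y = Y, ln2 = ln2$cache,
                heads = hcache, pool = pool)
  if (cfg$sat$ffn_expansion > 0) {
    f1 <- dense_fw(ln2$out, p$ffn$W1, p$ffn$b1)
    hf <- elu(f1$out)
    f2 <- dense_fw(hf, p$ffn$W2, p$ffn$b2)
    cache$ffn <- list(z = ln2$out, pre = f1$out, h = hf)
    out <- Y + f2$out
  } else {
    out <- ln2$out
  }
  list(out = out, cache = cache)
}

sat_layer_bw <- function(dout, p, cfg, B, cc) {
  n <- cfg$L2; F2 <- cfg$F2
  nh <- cfg$sat$n_heads; dk <- F2 %/% nh
  k <- cfg$top_k; ks <- k * cfg$partition$s
  pool <- cc$pool
  g <- list()
  if (cfg$sat$ffn_expansion > 0) {
    dY <- dout
    df2 <- dense_bw(dout, p$ffn$W2, cc$ffn$h)
    g$ffn <- list(W2 = df2$dW, b2 = df2$db)
    dhf <- df2$dx * elu_grad(cc$ffn$pre)
    df1 <- dense_bw(dhf, p$ffn$W1, cc$ffn$z)
    g$ffn$W1 <- df1$dW
    g$ffn$b1 <- df1$db
    ln2b <- layernorm_bw(df1$dx, p$ln2$gamma, cc$ln2)
    dY <- dY + ln2b$dx
  } else {
    ln2b <- layernorm_bw(dout, p$ln2$gamma, cc$ln2)
    dY <- ln2b$dx
  }
  g$ln2 <- list(gamma = ln2b$dgamma, beta = ln2b$dbeta)
  dXf_res <- dY
  dproj <- dropout_bw(dY, cc$drop)
  dd <- dense_bw(dproj, p$Wo, cc$H)
  g$Wo <- dd$dW; g$bo <- dd$db
  dH <- dd$dx
  dQ <- matrix(0, n * B, F2)
  dK <- matrix(0, n * B, F2)
  dV <- matrix(0, n * B, F2)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * n + seq_len(n)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      hc <- cc$heads[[(b - 1L) * nh + h]]
      Qb <- cc$Q[rows, cols, drop = FALSE]
      Kb <- cc$K[rows, cols, drop = FALSE]
      Vb <- cc$V[rows, cols, drop = FALSE]
      Kavg <- pool %*% Kb
      Vavg <- pool %*% Vb
      dO <- dH[rows, cols, drop = FALSE]
      P1 <- hc$P1; P2 <- hc$P2; idx <- hc$idx
      # aggregation path
      dP1 <- tcrossprod(dO, Vavg)
      dVavg <- crossprod(P1, dO)
      dS1 <- P1 * (dP1 - rowSums(dP1 * P1))
      dQb <- dS1 %*% Kavg / sqrt(dk)
      dKavg <- crossprod(dS1, Qb) / sqrt(dk)
      dKb <- crossprod(pool, dKavg)
      dVb <- crossprod(pool, dVavg)
      # top path
      flat <- as.vector(t(idx))
      dP2 <- matrix(rowSums(Vb[flat, , drop = FALSE] *
                              dO[rep(seq_len(n), each = ks), , drop = FALSE]),
                    n, ks, byrow = TRUE)
      dS2 <- P2 * (dP2 - rowSums(dP2 * P2))
      for (j in seq_len(ks)) {
        dQb <- dQb + (dS2[, j] / sqrt(dk)) * Kb[idx[, j], , drop = FALSE]
        rsK <- rowsum(dS2[, j] / sqrt(dk) * Qb, idx[, j])
        tk <- as.integer(rownames(rsK))
        dKb[tk, ] <- dKb[tk, ] + rsK
        rsV <- rowsum(P2[, j] * dO, idx[, j])
        tv <- as.integer(rownames(rsV))
        dVb[tv, ] <- dVb[tv, ] + rsV
      }
      dQ[rows, cols] <- dQ[rows, cols] + dQb
      dK[rows, cols] <- dK[rows, cols] + dKb
      dV[rows, cols] <- dV[rows, cols] + dVb
    }
  }
  g$Wq <- crossprod(cc$ln1_out, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cc$ln1_out, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cc$ln1_out, dV); g$bv <- colSums(dV)
  dXln <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  ln1b <- layernorm_bw(dXln, p$ln1$gamma, cc$ln1)
  g$ln1 <- list(gamma = ln1b$dgamma, beta = ln1b$dbeta)
  # flatten order must mirror init_params exactly
  keys <- c("ln1", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "ln2")
  if (cfg$sat$ffn_expansion > 0) {
    g$ffn <- g$ffn[c("W1", "b1", "W2", "b2")]
    keys <- c(keys, "ffn")
  }
  list(dx = dXf_res + ln1b$dx, grads = g[keys])
}

# ---- backward pass ----------------------------------------------------------

# dlogits: [B, n_classes]. Returns grads with the same structure as params.
apc_backward <- function(params, cache, dlogits, cfg) {
  B <- cache$B
  T <- cfg$T; C <- cfg$C
  F1 <- cfg$F1; F2 <- cfg$F2; L1 <- cfg$L1; L2 <- cfg$L2
  D <- F2 %/% F1
  grads <- list()

  pc <- params$clf
  if (cfg$classifier_hidden > 0) {
    d2 <- dense_bw(dlogits, pc$W2, cache$clf$hin)
    dh <- dropout_bw(d2$dx, cache$clf$hdrop) * elu_grad(cache$clf$h_pre)
    d1 <- dense_bw(dh, pc$W1, cache$clf$Fl)
    grads$clf <- list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db)
    dFl <- d1$dx
  } else {
    d1 <- dense_bw(dlogits, pc$W, cache$clf$Fl)
    grads$clf <- list(W = d1$dW, b = d1$db)
    dFl <- d1$dx
  }
  dXf <- matrix(aperm(array(dFl, c(B, L2, F2)), c(2L, 1L, 3L)), L2 * B, F2)

  grads$sat <- vector("list", cfg$sat$n_layers)
  for (l in rev(seq_len(cfg$sat$n_layers))) {
    sb <- sat_layer_bw(dXf, params$sat[[l]], cfg, B, cache$sat[[l]])
    dXf <- sb$dx
    grads$sat[[l]] <- sb$grads
  }

  dtokens <- array(dXf, c(L2, B, F2))
  grads$pae <- list(pos = colSums(aperm(dtokens, c(2L, 1L, 3L))))
  dim(grads$pae$pos) <- c(L2, F2)
  ddrop <- dropout_bw(dtokens, cache$pae$drop)
  dpool <- pool_time_bw(ddrop, cache$pae$pool)
  Lc <- 3L * L1
  dpre <- matrix(dpool, Lc * B, F2) * elu_grad(cache$pae$pre)
  pp <- params$pae
  bn1b <- batchnorm_bw(dpre, pp$bn1$gamma, cache$pae$bn1)
  bn2b <- batchnorm_bw(dpre, pp$bn2$gamma, cache$pae$bn2)
  grads$pae$bn1 <- list(gamma = bn1b$dgamma, beta = bn1b$dbeta)
  grads$pae$bn2 <- list(gamma = bn2b$dgamma, beta = bn2b$dbeta)
  c1b <- conv_multimap_bw(t(bn1b$dx), pp$conv1$W, cache$pae$c1)
  c2b <- conv_multimap_bw(t(bn2b$dx), pp$conv2$W, cache$pae$c2)
  grads$pae$conv1 <- list(W = c1b$dW, b = c1b$db)
  grads$pae$conv2 <- list(W = c2b$dW, b = c2b$db)
  dCc <- c1b$dA + c2b$dA
  grads$pae <- grads$pae[c("conv1", "conv2", "bn1", "bn2", "pos")]

  # split concatenation, CBAM backward, AFR interaction backward
  grads$branches <- vector("list", 3L)
  dSum <- matrix(0, L1 * B, F2)
  for (i in 1:3) {
    dci <- matrix(dCc[((i - 1L) * L1 + 1L):(i * L1), , , drop = FALSE],
                  L1 * B, F2)
    cb <- cbam_bw(dci, params$branches[[i]]$cbam, cache$branches[[i]]$cbam)
    grads$branches[[i]] <- list(cbam = cb$grads)
    dSum <- dSum + cb$dS
  }

  for (i in 1:3) {
    pb <- params$branches[[i]]
    bc <- cache$branches[[i]]
    dbr <- dropout_bw(array(dSum, c(L1, B, F2)), bc$drop)
    dact <- matrix(pool_time_bw(dbr, bc$pool), T * B, F2)
    dpre <- dact * elu_grad(bc$pre_elu)
    bnb <- batchnorm_bw(dpre, pb$bn$gamma, bc$bn)
    gb <- list(bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
    dZ2 <- bnb$dx                                  # [T*B, F2]
    dbs <- colSums(dZ2)
    if (cfg$spatial_mode == "depthwise") {
      dWs <- matrix(0, F2, C)
      dT <- matrix(0, T * B * C, F1)
      for (f1 in seq_len(F1)) {
        rows <- (f1 - 1L) * D + seq_len(D)
        dCols <- dZ2[, rows, drop = FALSE]         # [T*B, D]
        M <- matrix(bc$t_out[, f1], T * B, C)
        dWs[rows, ] <- crossprod(dCols, M)
        dT[, f1] <- dCols %*% pb$sconv$W[rows, , drop = FALSE]
      }
    } else {
      dWs <- crossprod(dZ2, bc$sp_in)              # [F2, F1*C]
      dMin <- dZ2 %*% pb$sconv$W                   # [T*B, F1*C]
      dT <- matrix(aperm(array(dMin, c(T * B, F1, C)), c(1L, 3L, 2L)),
                   T * B * C, F1)
    }
    gb$sconv <- list(W = dWs, b = dbs)
    tb <- conv_temporal_bw(dT, pb$tconv$W, bc$tconv)
    gb$tconv <- list(W = tb$dW, b = tb$db)
    grads$branches[[i]]$tconv <- gb$tconv
    grads$branches[[i]]$sconv <- gb$sconv
    grads$branches[[i]]$bn <- gb$bn
    grads$branches[[i]] <- grads$branches[[i]][c("tconv", "sconv", "bn",
                                                 "cbam")]
  }
  grads[c("branches", "pae", "sat", "clf")]
}

#' Mean cross-entropy loss
#'
#' Mean over the batch of the negative log predicted probability of the true
#' class, with a `1e-12` clamp inside the log.
#'
#' @param probs `[batch, n_classes]` matrix of predicted probabilities.
#' @param labels 0-based integer class labels.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels) {
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  -mean(log(pmax(p, 1e-12)))
}
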