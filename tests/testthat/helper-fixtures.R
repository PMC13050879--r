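# Small in-code fixtures shared across test files.

# Deterministic random epoch set.
make_epochs <- function(n = 4, C = 3, T = 100, n_cls = 2, fs = 250,
                        seed = 1, channel_names = NULL) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n * C * T), c(n, C, T)),
             labels = rep_len(0:(n_cls - 1L), n), fs = fs,
             channel_names = channel_names %||%
               channel_subset("all_22")[seq_len(C)],
             meta = list(n_classes = n_cls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny architecture used wherever a full-size network would be wasteful.
tiny_config <- function(n_classes = 2, C = 2, sat_layers = 1,
                        top_k = 1, window = 2, stride = 1, ...) {
  model_config(C = C, T = 40, n_classes = n_classes, fs = 20, F1 = 2,
               F2 = 4, pool1 = 10, pae_kernels = c(3, 5), pool2 = 3,
               dropout = 0, cbam_reduction = 2,
               sat = sat_config(d_model = 4, n_heads = 2,
                                n_layers = sat_layers, window = window,
                                stride = stride, top_k = top_k,
                                dropout = 0),
               ...)
}

tiny_epochs <- function(n = 6, cfg = tiny_config(), seed = 3) {
  make_epochs(n = n, C = cfg$C, T = cfg$T, n_cls = cfg$n_classes,
              fs = cfg$fs, seed = seed,
              channel_names = c("C3", "C4", "Cz")[seq_len(cfg$C)])
}

# Reference dense softmax attention used as the oracle in equivalence tests.
dense_attention <- function(Q, K, V) {
  S <- Q %*% t(K) / sqrt(ncol(Q))
  W <- exp(S - apply(S, 1, max))
  W <- W / rowSums(W)
  W %*% V
}
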