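# Seeded RNG helpers. Every stochastic stage draws from its own isolated
# RNG stream so that (a) results are a pure function of the stage seed and
# (b) package code never perturbs the caller's .Random.seed.

#' Derive a stage-specific seed from a global seed
#'
#' Mixes a global integer seed with a stage name into a new seed in
#' `[1, 2^31 - 2]`, so one user-facing seed fans out to independent,
#' reproducible per-stage streams.
#'
#' @param seed integer global seed.
#' @param stage character stage tag (e.g. `"noise"`, `"split"`).
#' @return integer derived seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# A self-contained RNG stream: methods swap the stream's own .Random.seed in
# and out around each draw, leaving the global RNG untouched.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())

  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    norm    = function(n) with_state(stats::rnorm(n)),
    unif    = function(n) with_state(stats::runif(n)),
    int     = function(max, n) with_state(sample.int(max, n, replace = TRUE)),
    permute = function(n) with_state(sample.int(n, n)))
}

# Numerically stable row-wise softmax of a matrix.
softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0))
sigmoid <- function(x) 1 / (1 + exp(-x))
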