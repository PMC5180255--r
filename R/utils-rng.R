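# Self-contained RNG streams. Each stream owns a saved .Random.seed state so
# that simulations are reproducible per (seed) argument and never disturb --
# nor depend on -- the caller's global RNG state.

rng_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  e
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

rng_runif <- function(rng, n = 1) with_rng(rng, stats::runif(n))

rng_sample <- function(rng, x, size = NULL, replace = FALSE) {
  with_rng(rng, {
    if (is.null(size)) sample(x, replace = replace)
    else sample(x, size = size, replace = replace)
  })
}

# Derive a reproducible sub-seed from a base seed and a stage label; kept
# within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483647L
}
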