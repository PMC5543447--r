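`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 32-bit sub-seed derivation so one master seed fans out to
## every randomised stage without correlated streams.
child_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  ## multiplier kept small so h * 69069 stays exact in double arithmetic
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 12345) %% 2147483647
  as.integer(h)
}

## Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
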