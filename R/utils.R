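# internal helpers shared across modules

# Run `expr` under a local RNG stream; the caller's .Random.seed is restored
# on exit so package functions never perturb user-level reproducibility.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# numerically safe logit of probabilities, clipped away from {0, 1}
clippedLogit <- function(p, eps = 1e-6) {
  qlogis(pmin(pmax(p, eps), 1 - eps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic sub-seed derivation: keeps derived seeds inside 32-bit range
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}
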