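# Internal helpers: seed derivation, RNG scoping, validation.

# Deterministically derive a 31-bit sub-stream seed from a master seed and a
# stream id. Linear congruential mix; exact in doubles (all intermediates
# < 2^53). Distinct (master, stream) pairs map to distinct-enough seeds for
# independent substreams per cell / per replicate.
derive_seed <- function(master, stream) {
  master <- as.numeric(master) %% 2147483647
  stream <- as.numeric(stream) %% 2147483647
  s <- (master * 48271 + stream * 16807 + 1013904223) %% 2147483647
  s <- (s * 69621 + 3039177861) %% 2147483647
  as.integer(s)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
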