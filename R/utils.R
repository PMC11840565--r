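# Internal helpers: seeded RNG scoping and deterministic seed streams.

# Evaluate `code` under a temporary RNG state; the caller's .Random.seed is
# restored afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent sub-seed from (seed, stream).  Linear congruential
# mix kept below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  k <- as.numeric(stream) %% 2147483647
  as.integer((s * 48271 + k * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
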