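# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded package functions never perturb the user's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically mix a master seed with a stream of integer tags
# (chain index, region rank, permutation number, ...) into a new seed.
# Kept strictly below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(master, ...) {
  tags <- c(master, ...)
  m <- 2147483647
  s <- 0
  for (k in tags) {
    k <- abs(as.numeric(k)) %% m
    s <- (s * 69069 + k + 1) %% m
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
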