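# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic operations in the package
# funnel through this so that a user-supplied seed fully determines output
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive `n` independent sub-seeds from a master seed.  Sub-seeds stay below
# .Machine$integer.max and are a pure function of `seed`.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
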