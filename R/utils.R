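#' Internal helpers shared across modules
#' @noRd
NULL

# Evaluate `expr` under a temporary RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic operations in the package
# take explicit seeds and route through here; nothing consumes global RNG
# state as a side effect.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#

# Derive a deterministic stream of sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Circularly delay every row of a channels x samples matrix by `s` samples.
rotate_rows <- function(mat, s) {
  n <- ncol(mat)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(mat)
  idx <- c((n - s + 1):n, 1:(n - s))
  mat[, idx, drop = FALSE]
}

# Round half away from zero (the usual table-printing convention, unlike
# round()'s round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
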