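# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Clip negative components to zero and renormalise to unit sum.
# Counts clips in the "woundloop.simplex_clips" option so long runs can report
# how often the unconstrained control pushed the state off the simplex.
project_simplex <- function(z, count = TRUE) {
  if (all(z >= 0)) {
    s <- sum(z)
    if (abs(s - 1) < 1e-12) return(z)
    return(z / s)
  }
  if (count) {
    n <- getOption("woundloop.simplex_clips", 0L)
    options(woundloop.simplex_clips = n + 1L)
  }
  z[z < 0] <- 0
  s <- sum(z)
  if (s <= 0) abort("state collapsed to the zero vector; cannot renormalise")
  z / s
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# Linear interpolation of the first up-crossing of `threshold` by `y` over `x`.
first_crossing <- function(x, y, threshold) {
  if (y[1] >= threshold) return(x[1] * 0)
  idx <- which(y >= threshold)
  if (length(idx) == 0L) return(NA_real_)
  j <- idx[1]
  x[j - 1] + (x[j] - x[j - 1]) * (threshold - y[j - 1]) / (y[j] - y[j - 1])
}
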