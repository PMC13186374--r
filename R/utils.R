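#' Derive a child seed from a master seed
#'
#' Counter-based seed derivation: each (master seed, index path) pair maps
#' to a stable 31-bit seed, so cohorts, rater panels and cross-validation
#' runs can be extended without reshuffling earlier items.
#'
#' @param seed Master seed (integer).
#' @param ... Integer indices identifying the child stream
#'   (e.g. class, patient, signal).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(42, 1, 3)
childSeed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.double(seed) %% 2147483647) + 1
  for (k in idx) {
    h <- (h * 48271 + (as.double(k) + 1) * 16807 + 11) %% 2147483647
  }
  as.integer(h + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

.assertScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number", call. = FALSE)
  if (positive && x <= 0)
    stop(name, " must be positive", call. = FALSE)
  invisible(x)
}

.assertRange <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop(name, " must be a numeric range c(lo, hi) with lo <= hi",
         call. = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
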