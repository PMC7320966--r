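# Internal helpers shared across the pipeline.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All exported stochastic operations
# funnel their seed through here so that a run never perturbs the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of a master seed into per-stage / per-iteration
#' seeds via a multiplicative congruential scheme, kept strictly below
#' `2^31` so the result is always a valid R integer.  The pipeline derives
#' every stage's seed this way, so stages are independently reproducible.
#'
#' @param base Integer master seed.
#' @param ... Integer indices (stage number, iteration number, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(base, ...) {
  idx <- c(...)
  x <- as.double(base %% 2147483647L)
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop3c <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop3c(sprintf("`%s` must be a single finite number in [%s, %s]",
                   name, format(lower), format(upper)))
  }
  invisible(x)
}
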