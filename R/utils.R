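#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit seed and leave the
#' caller's global RNG state untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# number of 300 ms segments in `duration_s`, erroring unless it divides evenly
#' @keywords internal
n_segments <- function(duration_s, segment_s = 0.3) {
  n <- duration_s / segment_s
  if (abs(n - round(n)) > 1e-9) {
    stopf("duration (%g s) must be a multiple of the %g s segment length",
          duration_s, segment_s)
  }
  as.integer(round(n))
}
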