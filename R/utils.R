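#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so stochastic routines are pure functions of their seed
#' without clobbering the global stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite `seed` is required for stochastic computations",
         call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 4L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
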