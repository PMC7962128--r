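#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state so callers' randomness is untouched.
#' All stochastic operations in the package route their draws through this
#' helper, which is what makes every pipeline stage bit-reproducible for a
#' fixed seed.
#'
#' @param seed integer seed (must be below 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) {
    stop("seed must have absolute value below 2^31", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Round half away from zero for report display
#'
#' Base `round()` rounds half to even; published tables round half up, so
#' report printers use this instead. Values are only rounded for display,
#' never before computation.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @keywords internal
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
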