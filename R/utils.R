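#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the previous
#' global RNG state, so seeded generators never leak state into (or read
#' state from) the caller's session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding to integers: 0.5 goes to 1, -0.5 to -1. Used for
#' all reported integer percents and scaled brightness values (base R's
#' `round()` rounds half to even, which does not reproduce the reporting
#' convention).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_out(c(0.5, 1.5, -0.5, 2.4))
round_half_out <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# shared scalar validators -------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"),
         call. = FALSE)
  }
  x
}

check_count <- function(x, name, lower = 1L) {
  check_scalar(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  as.integer(x)
}
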