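# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom stats plogis qlogis lm coef rexp rnorm runif rpois sd var
#' @importFrom utils read.csv write.csv head tail
## usethis namespace: end
NULL

# Round half away from zero (commercial rounding), as opposed to R's
# round-half-even. Used for the target-score rule so 39.9 -> 40 and 0.5 -> 1.
round_half_up <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derived from a parent seed and a stream index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is_scalar_number(x)) {
    stop_domain("'%s' must be a single finite number", name)
  }
  if (x < lo || x > hi) {
    stop_domain("'%s' must be in [%s, %s], got %s", name, lo, hi, x)
  }
  if (integer && x != round(x)) {
    stop_domain("'%s' must be an integer, got %s", name, x)
  }
  invisible(x)
}
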