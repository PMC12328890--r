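# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how the
#' descriptive tables in the phonetics literature are typeset (5.145 -> 5.15,
#' -2.785 -> -2.79), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of the time at which y crosses `level` between
# samples i and i+1. Assumes y[i] and y[i+1] bracket the level.
interp_crossing <- function(t, y, i, level) {
  dy <- y[i + 1] - y[i]
  if (dy == 0) return(t[i])
  t[i] + (level - y[i]) / dy * (t[i + 1] - t[i])
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x > 0
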