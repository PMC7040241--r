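# Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Base R `round()` rounds half to even; published clinical tables almost
#' always round half up, so reconstruction of printed percentages needs the
#' half-up convention explicitly.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be 0).
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Score comparisons use an absolute tolerance because the score lattice is
# decimal: 0.2 + 0.5 must count as >= 0.7 despite binary rounding.
SCORE_TOL <- 1e-9

#' @keywords internal
gte_tol <- function(x, cutoff, tol = SCORE_TOL) x >= cutoff - tol

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
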