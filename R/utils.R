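#' Round half away from zero
#'
#' Display rounding used throughout the dashboard tables. Unlike [base::round()]
#' (banker's rounding), ties go away from zero, so `round_half_away(62.5)` is
#' `63` and `round_half_away(-32.5)` is `-33`. Internal pipeline values are
#' never rounded; this is applied only when formatting results.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits`.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop with a named condition class so callers/tests can catch precisely
abort_doughnut <- function(msg, class) {
  rlang::abort(msg, class = c(class, "doughnut_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
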