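#' Percentage with half-up rounding
#'
#' Computes `100 * n / d` rounded half-up to a fixed number of decimals.
#' Base [round()] rounds half to even; published tables in this domain are
#' rounded half-up (10/23 prints as 43.5), so all percentage cells in this
#' package go through this helper.
#'
#' @param n Numerator (numeric, vectorized).
#' @param d Denominator (numeric, vectorized, `> 0`).
#' @param decimals Number of decimals kept (default 1).
#' @return Numeric vector of rounded percentages; `NA` where `d` is 0
#'   (an undefined value, never coerced to 0).
#' @examples
#' percent(10, 23)  # 43.5
#' percent(36, 37)  # 97.3
#' @export
percent <- function(n, d, decimals = 1L) {
  stopifnot(is.numeric(n), is.numeric(d))
  out <- round_half_up(100 * n / d, decimals)
  out[rep_len(d == 0, length(out))] <- NA_real_
  out
}

#' Round half-up
#'
#' @param x Numeric vector.
#' @param decimals Decimals kept.
#' @return `x` rounded half-up (0.5 always away from zero).
#' @export
round_half_up <- function(x, decimals = 1L) {
  p <- 10^decimals
  # small epsilon absorbs binary representation error (e.g. 2.675 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a p-value the way clinical tables print it
#'
#' Values below 0.0005 display as "0.000"; full precision is retained by the
#' caller — this is presentation only.
#'
#' @param p Numeric p-values.
#' @return Character vector, three decimals.
#' @export
format_pvalue <- function(p) {
  formatC(round_half_up(p, 3L), format = "f", digits = 3)
}

# internal: stop with a classed condition so tests can assert on error type
vt_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "vtburden_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a
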