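#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for every printed percentage and Mb size in the reports this package
#' reproduces (base [round()] uses banker's rounding and would turn 0.5 into 0).
#'
#' @param x numeric vector (non-negative values expected in this package).
#' @param digits integer, decimals to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.25, 0.35), 1) # 0.3 0.4
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against 1/1e6-style binary representation error
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage with half-up display rounding
#'
#' Formats the (n, N) pairs printed throughout clinical CNV cohort tables:
#' 100 * n / N rounded half-up to one decimal. An empty denominator is
#' undefined, not zero, and returns `NA_real_`.
#'
#' @param n numerator count(s).
#' @param N denominator count(s).
#' @param digits decimals to keep (default 1, the tables' convention).
#' @return numeric vector of percentages, `NA` where `N == 0`.
#' @examples
#' pctHalfUp(24, 104) # 23.1
#' pctHalfUp(0, 0)    # NA
#' @export
pctHalfUp <- function(n, N, digits = 1) {
  out <- roundHalfUp(100 * n / N, digits)
  out[rep_len(N == 0, length(out))] <- NA_real_
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix, no call chaff
abort <- function(...) stop(..., call. = FALSE)

assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    abort(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}
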