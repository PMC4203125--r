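# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise sample variances of a numeric matrix (denominator n - 1)
#' @noRd
row_vars <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two columns to compute a variance")
  rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L)
}

#' Half-up rounding to whole units (12.5 -> 13, -12.5 -> -13)
#'
#' Used for reporting lags in whole days. Base `round()` rounds half to even
#' (6.5 -> 6), which does not match how lag tables are conventionally printed.
#'
#' @param x numeric vector.
#' @return numeric vector of whole numbers.
#' @examples
#' round_half_up(c(6.5, 9.9, 13.0, 1.4))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

assert_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
  }
  as.integer(x)
}

assert_alpha <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must lie strictly between 0 and 1", name), call. = FALSE)
  }
  x
}

#' Evaluate a polynomial given coefficients in increasing order of power
#' @noRd
poly_eval <- function(coefs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1L)
  out
}

#' Derivative coefficients of a polynomial (increasing powers)
#' @noRd
poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1L] * seq_len(length(coefs) - 1L)
}
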