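# Empirical-Bayes variance shrinkage for the moderated paired t-test.
#
# Per-gene sample variances s^2 with d df are modelled as scaled F draws
# around a prior scale s0^2 with prior df d0. (d0, s0^2) are estimated by
# method of moments on log variances: if s^2 ~ s0^2 F(d, d0) then
#   E[log s^2]  = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#   Var[log s^2] = trigamma(d/2) + trigamma(d0/2),
# so trigamma(d0/2) is the excess of the observed log-variance spread over
# the sampling component trigamma(d/2); a non-positive excess means no
# detectable gene-to-gene variance heterogeneity (d0 = Inf).

#' Estimate the variance prior (d0, s0^2) and posterior variances
#'
#' @param s2 per-gene sample variances.
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @return list with `df_prior`, `var_prior` and `var_post`, where
#'   `var_post = (d0 s0^2 + d s^2) / (d0 + d)` (equal to `s0^2` when
#'   `d0 = Inf`).
#' @examples
#' squeeze_variances(rchisq(100, 3) / 3, df = 3)$df_prior
#' @export
squeeze_variances <- function(s2, df) {
  if (df < 1) stop("'df' must be >= 1")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least two positive variances to fit the prior")
  z <- log(s2[ok])
  emean <- mean(z) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no detectable heterogeneity: with an infinite prior the common scale
    # is estimated by the arithmetic mean of the sample variances
    df_prior <- Inf
    var_prior <- mean(s2[ok])
  }
  list(
    df_prior = df_prior,
    var_prior = var_prior,
    var_post = posterior_variance(s2, df, df_prior, var_prior)
  )
}

posterior_variance <- function(s2, df, df_prior, var_prior) {
  s2 <- pmax(s2, 0)
  if (is.infinite(df_prior)) rep(var_prior, length(s2))
  else (df_prior * var_prior + df * s2) / (df_prior + df)
}

#' Solve trigamma(y) = x by Newton iteration
#' @noRd
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
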