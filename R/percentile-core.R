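#' Conditional exceedance level within the positive component
#'
#' For a delta-lognormal population with zero probability `delta_prime`,
#' the p-th quantile of the whole distribution is the eta-th quantile of
#' the lognormal positive part, with
#' `eta = (p - delta_prime) / (1 - delta_prime)`. Requires
#' `p > delta_prime`; at or below the zero mass the quantile is 0 and no
#' log-scale percentile exists.
#'
#' @param p target percentile level in (0, 1).
#' @param delta_prime zero probability (or its estimate), in `[0, 1)`.
#' @return value in (0, 1).
#' @export
eta_level <- function(p, delta_prime) {
  stopifnot(p > 0, p < 1, delta_prime >= 0, delta_prime < 1)
  if (any(p <= delta_prime))
    stop("percentile at zero mass: p <= delta_prime, the quantile is 0")
  (p - delta_prime) / (1 - delta_prime)
}

#' Log-scale percentile estimate for one group
#'
#' `lambda = ybar1 + qnorm(eta) * sqrt(s2_1)` with the plug-in
#' `delta_hat = n0/n` inside eta. The original-scale percentile estimate is
#' `exp(lambda)`.
#'
#' @param summary one-row group summary (see [dln_summarize()]), or a
#'   `dln_summary` with several rows (vectorised over rows).
#' @param p percentile level in (0, 1).
#' @return numeric vector of log-scale percentile estimates.
#' @export
lambda_point <- function(summary, p) {
  z <- stats::qnorm(eta_level(p, summary$delta_hat))
  summary$ybar1 + z * sqrt(summary$s2_1)
}

#' Asymptotic variance of the back-transformed log-mean estimator
#'
#' Evaluates, term by term, the variance expression used to weight the
#' per-group percentile estimates. Its arguments are the log-scale mean and
#' variance of the positive part and the positive-sample size.
#'
#' @param mu log-scale mean.
#' @param sigma2 log-scale variance (> 0).
#' @param n1 positive-sample size (>= 2).
#' @return variance (vectorised over the inputs).
#' @export
var_ybar1 <- function(mu, sigma2, n1) {
  denom <- 2 * (n1 + 4) * (n1 - 1) + 3 * sigma2
  e <- exp((n1 - 1) * sigma2 / denom)
  exp(mu)^2 * (sigma2 / n1 + 1) * e^2 *
    ((2 * (n1 - 1) * sigma2^2 / n1) /
       (2 * (n1 + 4) * (n1 - 1) + 6 * sigma2^2 / n1) + 1) -
    (exp(mu) * e)^2
}

#' Asymptotic variance of the log-scale sample variance estimator
#'
#' @inheritParams var_ybar1
#' @return variance (vectorised).
#' @export
var_s2_1 <- function(mu, sigma2, n1) {
  (2 * sigma2 / n1 * exp(4 * mu + 2 * sigma2)) *
    (2 * (exp(sigma2) - 1)^2 + sigma2 * (2 * exp(sigma2) - 1)^2)
}

#' Variance of the per-group log-scale percentile estimate
#'
#' Two printed forms of this variance circulate in the source material and
#' differ in whether the `z_p^2 * Var(S^2)` term is multiplied by
#' `lambda^2`:
#' * `"additive"` (default): `lambda^2 * var_ybar + z_p^2 * var_s2`;
#' * `"factored"`: `lambda^2 * (var_ybar + z_p^2 * var_s2)`.
#'
#' The additive form is the default because it is the one used consistently
#' by the fiducial and both Bayesian constructions.
#'
#' @param lambda_value log-scale percentile estimate.
#' @param var_ybar,var_s2 variance components (see [var_ybar1()],
#'   [var_s2_1()]).
#' @param p percentile level; `z_p = qnorm(p)`.
#' @param form `"additive"` or `"factored"`.
#' @return variance (vectorised).
#' @export
var_lambda <- function(lambda_value, var_ybar, var_s2, p,
                       form = c("additive", "factored")) {
  form <- match.arg(form)
  zp2 <- stats::qnorm(p)^2
  switch(form,
    additive = lambda_value^2 * var_ybar + zp2 * var_s2,
    factored = lambda_value^2 * (var_ybar + zp2 * var_s2)
  )
}

#' Precision-weighted common log-percentile
#'
#' `lambda_p = sum(lambda_i / v_i) / sum(1 / v_i)`; the common percentile on
#' the original scale is `theta = exp(lambda_p)`. A convex combination, so
#' the result always lies within the range of `lambdas` and is invariant to
#' rescaling all variances by a positive constant.
#'
#' @param lambdas per-group log-scale percentile estimates.
#' @param variances matching positive variances.
#' @return list with `lambda_p` and `theta`.
#' @export
weighted_common <- function(lambdas, variances) {
  stopifnot(length(lambdas) == length(variances), length(lambdas) >= 1)
  if (any(variances <= 0)) stop("all variances must be > 0")
  w <- 1 / variances
  lambda_p <- sum(lambdas * w) / sum(w)
  list(lambda_p = lambda_p, theta = exp(lambda_p))
}

# Row-wise weighted combination of an m x k draw matrix with m x k weights.
.combine_draws <- function(lambda_mat, weight_mat) {
  rowSums(lambda_mat * weight_mat) / rowSums(weight_mat)
}

# Shared validation for the interval methods.
.check_summaries <- function(summaries, p) {
  stopifnot(is.data.frame(summaries),
            all(c("n", "n0", "n1", "ybar1", "s2_1", "delta_hat") %in%
                  names(summaries)))
  bad <- summaries$delta_hat >= p
  if (any(bad)) {
    labs <- if ("label" %in% names(summaries))
      summaries$label[bad] else which(bad)
    stop("percentile at zero mass for group(s) ",
         paste(labs, collapse = ", "),
         ": estimated zero probability >= p")
  }
  invisible(summaries)
}
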