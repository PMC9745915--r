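#' Truncated-beta fiducial draw for the zero probability
#'
#' Inverse-CDF draw from a Beta(n0 + 1/2, n1 + 1/2) distribution truncated
#' to `[0, p]`: `qbeta(v * pbeta(p, a, b), a, b)` with `a = n0 + 0.5`,
#' `b = n1 + 0.5`. At `v = 0` the draw is 0; at `v = 1` it is `p`, so the
#' induced exceedance level never falls at or below zero mass.
#'
#' @param n0,n1 zero and positive counts.
#' @param p truncation point (the target percentile level).
#' @param v uniform variate(s) in `[0, 1]`.
#' @return draw(s) in `[0, p]`.
#' @export
truncated_beta_delta <- function(n0, n1, p, v) {
  stopifnot(all(v >= 0 & v <= 1))
  a <- n0 + 0.5
  b <- n1 + 0.5
  # log-space inverse CDF: pbeta(p, a, b) underflows to 1 when p sits far in
  # the upper tail, which would send v = 1 to 1 instead of p
  draw <- stats::qbeta(log(v) + stats::pbeta(p, a, b, log.p = TRUE),
                       a, b, log.p = TRUE)
  pmin(draw, p)
}

#' Fiducial pivot for the log-scale variance
#'
#' `(n1 - 1) * s2_1 / chi2_draw` with `chi2_draw` a chi-square variate on
#' `n1 - 1` degrees of freedom.
#'
#' @param s2_1 observed log-scale variance of the positives.
#' @param n1 positive count.
#' @param chi2_draw chi-square draw(s), > 0.
#' @export
fgpq_sigma2 <- function(s2_1, n1, chi2_draw) {
  stopifnot(all(chi2_draw > 0))
  (n1 - 1) * s2_1 / chi2_draw
}

#' Fiducial pivot for the log-scale mean
#'
#' `ybar1 - (z / sqrt(u)) * sqrt((n1 - 1) * s2_1 / n1)`, the classical
#' generalized pivot for a normal mean, with `z` standard normal and `u`
#' chi-square on `n1 - 1` degrees of freedom.
#'
#' @param ybar1,s2_1 observed log-scale mean and variance of the positives.
#' @param n1 positive count.
#' @param z_draw standard normal draw(s).
#' @param u_draw chi-square draw(s) on `n1 - 1` df, > 0.
#' @export
fgpq_mu <- function(ybar1, s2_1, n1, z_draw, u_draw) {
  stopifnot(all(u_draw > 0))
  ybar1 - z_draw / sqrt(u_draw) * sqrt((n1 - 1) * s2_1 / n1)
}

#' Fiducial pivot for the log-scale percentile
#'
#' Combines the mean and variance pivots with a fiducial exceedance level:
#' `r_mu + sqrt(r_sigma2 / n1) * (z + qnorm(r_eta) * sqrt(n1)) / sqrt(u/(n1-1))`.
#' The trailing chi-square is normalised by its degrees of freedom, so for
#' `z = 0`, `r_eta = 1/2` the draw reduces to `r_mu`, and the
#' `qnorm(r_eta)` term carries scale `sqrt(r_sigma2)` as in the
#' single-sample pivot.
#'
#' @param r_mu,r_sigma2 mean and variance pivot draws.
#' @param n1 positive count.
#' @param z_draw standard normal draw(s).
#' @param u_draw chi-square draw(s) on `n1 - 1` df, > 0.
#' @param r_eta fiducial exceedance level(s) in (0, 1).
#' @export
fgpq_lambda <- function(r_mu, r_sigma2, n1, z_draw, u_draw, r_eta) {
  stopifnot(all(u_draw > 0), all(r_eta > 0 & r_eta < 1))
  r_mu + sqrt(r_sigma2) / sqrt(n1) *
    (z_draw + stats::qnorm(r_eta) * sqrt(n1)) / sqrt(u_draw / (n1 - 1))
}

#' Fiducial generalized confidence interval for the common percentile
#'
#' For each of `m` iterations and each group, draws independent chi-square,
#' normal and uniform variates, forms the fiducial pivots for the zero
#' probability, log-mean, log-variance and log-percentile, weights the
#' per-group percentile pivots by the reciprocal of their variance pivot,
#' and takes the equal-tailed empirical quantiles (type 7) of the combined
#' draws. Limits are exponentiated back to the data scale.
#'
#' Uses the global RNG; set a seed for reproducibility.
#'
#' @param summaries a `dln_summary` (one row per group).
#' @param p percentile level in (0, 1); every group must have
#'   `delta_hat < p`.
#' @param alpha one minus the confidence level.
#' @param m number of fiducial draws (>= 100).
#' @param variance_form see [var_lambda()].
#' @return A `dln_ci` object.
#' @examples
#' set.seed(7)
#' ci_fgci(summarize_groups(rainfall_fixture()), m = 1000)
#' @export
ci_fgci <- function(summaries, p = 0.95, alpha = 0.05, m = 1000,
                    variance_form = c("additive", "factored")) {
  variance_form <- match.arg(variance_form)
  .check_summaries(summaries, p)
  if (m < 100) stop("'m' must be at least 100")
  k <- nrow(summaries)
  lam <- w <- matrix(0, m, k)
  for (i in seq_len(k)) {
    n1 <- summaries$n1[i]; n0 <- summaries$n0[i]
    chi <- stats::rchisq(m, n1 - 1)          # variance pivot
    u_mu <- stats::rchisq(m, n1 - 1)         # mean pivot denominator
    u_lam <- stats::rchisq(m, n1 - 1)        # percentile pivot denominator
    z_mu <- stats::rnorm(m)
    z_lam <- stats::rnorm(m)
    v <- stats::runif(m)
    r_sigma2 <- fgpq_sigma2(summaries$s2_1[i], n1, chi)
    r_mu <- fgpq_mu(summaries$ybar1[i], summaries$s2_1[i], n1, z_mu, u_mu)
    r_delta <- truncated_beta_delta(n0, n1, p, v)
    r_eta <- (p - r_delta) / (1 - r_delta)
    lam[, i] <- fgpq_lambda(r_mu, r_sigma2, n1, z_lam, u_lam, r_eta)
    w[, i] <- 1 / var_lambda(lam[, i],
                             var_ybar1(r_mu, r_sigma2, n1),
                             var_s2_1(r_mu, r_sigma2, n1),
                             p, variance_form)
  }
  draws <- .combine_draws(lam, w)
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  point <- .point_estimate(summaries, p, variance_form)
  new_dln_ci("fgci", q, p, alpha, m = m, point = point)
}

# Point estimate exp(lambda_p) from the observed summaries.
.point_estimate <- function(summaries, p, variance_form) {
  lam <- lambda_point(summaries, p)
  v <- var_lambda(lam,
                  var_ybar1(summaries$ybar1, summaries$s2_1, summaries$n1),
                  var_s2_1(summaries$ybar1, summaries$s2_1, summaries$n1),
                  p, variance_form)
  weighted_common(lam, v)$theta
}
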