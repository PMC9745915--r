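# Independent duplicate implementations used as oracles. Written against the
# formulas directly, structured differently from the package code (explicit
# scalar term accumulation rather than vectorised composition).

oracle_var_ybar1 <- function(mu, sigma2, n1) {
  a <- exp(mu)^2
  b <- sigma2 / n1 + 1
  expo <- (n1 - 1) * sigma2 / (2 * (n1 + 4) * (n1 - 1) + 3 * sigma2)
  cc <- exp(expo)^2
  num <- 2 * (n1 - 1) * (sigma2^2 / n1)
  den <- 2 * (n1 + 4) * (n1 - 1) + 6 * sigma2^2 / n1
  d <- num / den + 1
  sub <- (exp(mu) * exp(expo))^2
  a * b * cc * d - sub
}

oracle_var_s2_1 <- function(mu, sigma2, n1) {
  f1 <- 2 * sigma2 / n1
  f2 <- exp(4 * mu + 2 * sigma2)
  g1 <- 2 * (exp(sigma2) - 1)^2
  g2 <- sigma2 * (2 * exp(sigma2) - 1)^2
  (f1 * f2) * (g1 + g2)
}

oracle_fgpq_lambda <- function(r_mu, r_sigma2, n1, z, u, r_eta) {
  scale <- sqrt(r_sigma2) / sqrt(n1)
  numer <- z + qnorm(r_eta) * sqrt(n1)
  denom <- sqrt(u / (n1 - 1))
  r_mu + scale * numer / denom
}

oracle_bs1_lambda <- function(mu, sigma2, n0, n1, z, u, v, p) {
  a <- n0 + 0.5; b <- n1 + 0.5
  qd <- qbeta(v * pbeta(p, a, b), a, b)
  qe <- (p - qd) / (1 - qd)
  mu + sqrt(sigma2 / n1) * (z + qnorm(qe) * sqrt(n1)) / sqrt(u / (n1 - 1))
}

# Noncentral-t quantile by root finding on the distribution function,
# independent of qt()'s quantile algorithm.
oracle_nct_quantile <- function(level, df, ncp) {
  uniroot(function(t) suppressWarnings(pt(t, df = df, ncp = ncp)) - level,
          interval = c(-100, 100), tol = 1e-10)$root
}

# Exhaustive shortest-window HPD for small draw sets.
oracle_hpd <- function(x, alpha) {
  x <- sort(x)
  m <- length(x)
  w <- ceiling((1 - alpha) * m)
  best <- c(x[1], x[w]); bestw <- x[w] - x[1]
  for (j in seq_len(m - w + 1)) {
    wd <- x[j + w - 1] - x[j]
    if (wd < bestw) { bestw <- wd; best <- c(x[j], x[j + w - 1]) }
  }
  best
}

# Random admissible group summary for property tests.
random_summary <- function(p = 0.95) {
  n1 <- sample(5:40, 1)
  n0 <- sample(0:5, 1)
  s <- data.frame(label = "r", n = n0 + n1, n0 = n0, n1 = n1,
                  ybar1 = rnorm(1), s2_1 = runif(1, 0.2, 3),
                  delta_hat = n0 / (n0 + n1), stringsAsFactors = FALSE)
  class(s) <- c("dln_summary", class(s))
  s
}

# Reference values printed with the original analysis of the rainfall data
# (per-region AIC table). Used to test the selection rule and to cross-check
# the fits for the four regions whose raw data are internally consistent.
ref_aic <- data.frame(
  distribution = c("normal", "lognormal", "gamma", "exponential"),
  Northern     = c(146.9695, 113.0194, 114.4763, 114.2356),
  Northeastern = c(156.6773, 115.0962, 118.5788, 124.2752),
  Central      = c(157.6655, 137.7288, 137.9854, 134.9935),
  Eastern      = c(138.4266, 102.1466, 104.0756, 106.5699),
  Southern     = c(163.5237, 135.4856, 133.4562, 135.0211),
  stringsAsFactors = FALSE
)
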