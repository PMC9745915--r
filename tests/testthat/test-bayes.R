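test_that("posterior draws have the conjugate moments", {
  s <- data.frame(label = "g", n = 30, n0 = 0, n1 = 30,
                  ybar1 = 0.4, s2_1 = 1, delta_hat = 0)
  set.seed(41)
  d <- draw_sigma2_mu(s, 1e5)
  # inverse-gamma mean: rate / (shape - 1)
  expect_equal(mean(d$sigma2), (29 * 1 / 2) / (29 / 2 - 1), tolerance = 0.02)
  expect_equal(mean(d$mu), 0.4, tolerance = 3 * sd(d$mu) / sqrt(1e5) * 2)
  set.seed(13); a <- draw_sigma2_mu(s, 10)
  set.seed(13); b <- draw_sigma2_mu(s, 10)
  expect_identical(a, b)
})

test_that("bs1 draw matches its oracle and endpoint behaviour", {
  s <- data.frame(label = "g", n = 25, n0 = 5, n1 = 20,
                  ybar1 = 1, s2_1 = 0.8, delta_hat = 0.2)
  # v -> 0 sends the zero-probability draw to 0 and eta to p
  lam0 <- bs1_lambda_draw(1, 0.8, s, 0, 19, 0, p = 0.95)
  expect_equal(lam0, 1 + sqrt(0.8 / 20) * qnorm(0.95) * sqrt(20) /
                 sqrt(19 / 19))
  set.seed(44)
  for (i in 1:10) {
    mu <- rnorm(1); s2 <- runif(1, 0.2, 2); z <- rnorm(1)
    u <- rchisq(1, 19); v <- runif(1)
    expect_equal(bs1_lambda_draw(mu, s2, s, z, u, v, 0.95),
                 oracle_bs1_lambda(mu, s2, 5, 20, z, u, v, 0.95),
                 tolerance = 1e-12)
  }
})

test_that("bs2 draw is an affine map of the posterior draws", {
  s <- data.frame(label = "g", n = 25, n0 = 5, n1 = 20,
                  ybar1 = 1, s2_1 = 0.8, delta_hat = 0.2)
  # sigma2 -> 0 limit collapses to mu
  expect_equal(bs2_lambda_draw(2.5, 1e-20, s), 2.5, tolerance = 1e-8)
  # the t quantile is a data constant: same slope for any draw
  l1 <- bs2_lambda_draw(0, 1, s)
  l2 <- bs2_lambda_draw(0, 4, s)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # eta = 1/2 gives the central t quantile
  sc <- data.frame(label = "g", n = 20, n0 = 18, n1 = 2,
                   ybar1 = 0, s2_1 = 1, delta_hat = 0.9)
  expect_equal(bs2_lambda_draw(0, 1, sc, p = 0.95, alpha = 0.05),
               qt(0.95, df = 1) / sqrt(2), tolerance = 1e-10)
})

test_that("hpd_interval finds the shortest contiguous window", {
  expect_equal(hpd_interval(1:100, 0.05), c(1, 95))  # tie-break: first window
  set.seed(46)
  x <- rnorm(1e6)
  h <- hpd_interval(x, 0.05)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.01)

  for (i in 1:20) {
    y <- rgamma(sample(20:200, 1), shape = 2)
    a <- runif(1, 0.02, 0.3)
    h <- oracle_hpd(y, a)
    got <- hpd_interval(y, a)
    expect_equal(got, h)
    # never wider than the equal-tailed window; contains >= (1-a) mass
    q <- quantile(y, c(a / 2, 1 - a / 2), names = FALSE)
    expect_lte(diff(got), diff(q) + 1e-12)
    expect_gte(sum(y >= got[1] & y <= got[2]),
               ceiling((1 - a) * length(y)))
  }
  expect_error(hpd_interval(1:10, 1.5), "alpha")
})

test_that("ci_bayes variants are reproducible and ordered", {
  s <- summarize_groups(rainfall_fixture())
  for (v in c("bs1", "bs2")) {
    set.seed(48); a <- ci_bayes(s, v, m = 500)
    set.seed(48); b <- ci_bayes(s, v, m = 500)
    expect_identical(a[c("L", "U")], b[c("L", "U")])
    expect_true(a$L > 0 && a$L < a$U)
  }
})

test_that("bs1 and fgci agree for large samples", {
  # flat-in-effect priors: the posterior and fiducial draws converge
  set.seed(51)
  x <- rdln(500, mu = 1, sigma2 = 0.5, delta_prime = 0.1)
  s <- dln_summarize(x)
  class(s) <- c("dln_summary", class(s))
  set.seed(52); f <- ci_fgci(s, m = 4000)
  set.seed(53); b <- ci_bayes(s, "bs1", m = 4000)
  expect_equal(f$log_L, b$log_L, tolerance = 0.05)
  expect_equal(f$log_U, b$log_U, tolerance = 0.05)
})
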