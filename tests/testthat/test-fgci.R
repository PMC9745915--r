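test_that("truncated beta draw hits its endpoints and is monotone", {
  expect_equal(truncated_beta_delta(6, 23, 0.95, 0), 0)
  expect_equal(truncated_beta_delta(6, 23, 0.95, 1), 0.95)
  grid <- seq(0, 1, by = 0.01)
  draws <- truncated_beta_delta(3, 12, 0.9, grid)
  expect_true(all(diff(draws) >= 0))
  expect_true(all(draws >= 0 & draws <= 0.9))
})

test_that("variance pivot recovers the observed value and scales linearly", {
  expect_equal(fgpq_sigma2(2.5, 16, 15), 2.5)
  expect_equal(fgpq_sigma2(5, 16, 3), 2 * fgpq_sigma2(2.5, 16, 3))
  # distributional check against the chi-square median
  set.seed(21)
  draws <- fgpq_sigma2(1.3, 25, rchisq(1e5, 24))
  expect_equal(median(draws), 24 * 1.3 / qchisq(0.5, 24), tolerance = 0.02)
})

test_that("mean pivot is centred and symmetric", {
  expect_equal(fgpq_mu(1.7, 2, 10, 0, 5), 1.7)
  u <- 7.3
  expect_equal(fgpq_mu(1.7, 2, 10, 1.2, u) - 1.7,
               -(fgpq_mu(1.7, 2, 10, -1.2, u) - 1.7))
  set.seed(22)
  draws <- fgpq_mu(1.7, 2, 10, rnorm(1e5), rchisq(1e5, 9))
  # Z symmetric and independent of the chi-square: mean is ybar1
  expect_equal(mean(draws), 1.7, tolerance = 3 * sd(draws) / sqrt(1e5) * 2)
})

test_that("percentile pivot reduces correctly and matches its oracle", {
  expect_equal(fgpq_lambda(2.2, 1.5, 12, 0, 11, 0.5), 2.2)
  lams <- vapply(c(0.3, 0.5, 0.7, 0.9), function(e)
    fgpq_lambda(1, 1, 10, 0.4, 9.1, e), numeric(1))
  expect_true(all(diff(lams) > 0))
  set.seed(23)
  for (i in 1:10) {
    args <- list(r_mu = rnorm(1), r_sigma2 = runif(1, 0.1, 3),
                 n1 = sample(5:30, 1), z = rnorm(1),
                 u = rchisq(1, 10), e = runif(1, 0.05, 0.95))
    expect_equal(
      fgpq_lambda(args$r_mu, args$r_sigma2, args$n1, args$z, args$u, args$e),
      oracle_fgpq_lambda(args$r_mu, args$r_sigma2, args$n1, args$z, args$u,
                         args$e),
      tolerance = 1e-12)
  }
})

test_that("ci_fgci is reproducible and well ordered", {
  s <- summarize_groups(rainfall_fixture())
  set.seed(31); a <- ci_fgci(s, m = 500)
  set.seed(31); b <- ci_fgci(s, m = 500)
  expect_identical(a[c("L", "U")], b[c("L", "U")])
  expect_true(a$L > 0 && a$L < a$U)
  expect_equal(a$length, a$U - a$L)
  expect_equal(a$L, exp(a$log_L))
  expect_error(ci_fgci(s, m = 50), "at least 100")

  # smaller alpha never narrows the interval on the same draw stream
  set.seed(31); wide <- ci_fgci(s, alpha = 0.01, m = 500)
  expect_lte(wide$log_L, a$log_L)
  expect_gte(wide$log_U, a$log_U)

  # p below a group's zero-mass estimate is rejected by name
  expect_error(ci_fgci(s, p = 0.2), "Northeastern")
})

test_that("single-group fgci covers the true percentile at its nominal rate", {
  # MC coverage oracle: one group, known truth
  set.seed(77)
  mu <- 1; s2 <- 0.5; dp <- 0.1; n <- 50; p <- 0.95
  theta <- qdln(p, mu, s2, dp)
  hits <- 0L; reps <- 300L
  for (r in seq_len(reps)) {
    x <- rdln(n, mu, s2, dp)
    s <- tryCatch(dln_summarize(x), error = function(e) NULL)
    if (is.null(s) || s$delta_hat >= p) { reps <- reps - 1L; next }
    class(s) <- c("dln_summary", class(s))
    ci <- ci_fgci(s, p = p, m = 400)
    hits <- hits + ((ci$L <= theta) && (theta <= ci$U))
  }
  coverage <- hits / reps
  expect_gt(coverage, 0.90)
  expect_lte(coverage, 1.0)
})
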