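test_that("summarize_posterior handles degenerate and reference cases", {
  s <- summarize_posterior(matrix(0.42, 100, 2))
  expect_equal(s$mean, 0.42)
  expect_equal(s$median, 0.42)
  expect_equal(s$cri_low, 0.42)
  expect_equal(s$cri_high, 0.42)
  expect_true(is.na(s$rhat))   # zero-variance draws: diagnostics unavailable

  set.seed(1)
  s2 <- summarize_posterior(matrix(rnorm(1e5), ncol = 2))
  expect_lt(abs(s2$cri_low - qnorm(0.025)), 0.05)  # normal quantile oracle
  expect_lt(abs(s2$cri_high - qnorm(0.975)), 0.05)
  expect_lt(s2$rhat, 1.01)
  expect_gt(s2$ess, 1e4)

  # single chain: rhat marked unavailable, summary still returned
  s3 <- summarize_posterior(rnorm(500))
  expect_true(is.na(s3$rhat))
  expect_true(is.na(s3$converged))

  expect_error(summarize_posterior(numeric(0)), "draws")
  expect_error(summarize_posterior(c(1, NA)), "finite")
})

test_that("rhat flags unmixed chains and passes mixed ones", {
  set.seed(2)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(rhat(bad), 1.2)
  expect_warning(summarize_posterior(bad), "converged")
})

test_that("prevalence rendering follows the percent [95% CI] style", {
  s <- list(mean = 0.21, cri_low = 0.07, cri_high = 0.34)
  expect_identical(format_prevalence(s), "21% [95% CI 7–34]")
})

test_that("contrast_strata quantifies differences between cells", {
  a <- rep(0.8, 100)
  b <- rep(0.2, 100)
  ct <- contrast_strata(a, b)
  expect_equal(ct$summary$mean, 0.6)
  expect_identical(ct$p_greater, 1)
  expect_true(ct$differs)

  self <- contrast_strata(a, a)
  expect_equal(self$summary$mean, 0)
  expect_false(self$differs)

  # closed-form oracle: P(A > B), A ~ Beta(8,4), B ~ Beta(4,8) independent
  oracle <- stats::integrate(function(x) dbeta(x, 8, 4) * pbeta(x, 4, 8),
                             0, 1)$value
  set.seed(10)
  mc <- contrast_strata(rbeta(4e4, 8, 4), rbeta(4e4, 4, 8))
  expect_lt(abs(mc$p_greater - oracle), 0.01)

  expect_error(contrast_strata(numeric(0), b), "empty")
  expect_error(contrast_strata(a, b[1:50]), "equal draw counts")
})
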