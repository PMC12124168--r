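test_that("dependency measures follow their definitions", {
  m <- dependency_measures(2L, 4L, 4L)
  expect_equal(m$ratio, 0.5)
  expect_identical(m$exceeds_flag, 0L)
  expect_warning(m2 <- dependency_measures(3L, 0L, 1L), "no working adults")
  expect_true(is.na(m2$ratio))
  expect_identical(m2$exceeds_flag, 1L)
  expect_error(dependency_measures(-1L, 2L, 2L), "non-negative")
  # vectorized, computed from raw counts independently
  suppressWarnings(mv <- dependency_measures(c(1L, 3L), c(2L, 0L), c(3L, 2L)))
  expect_equal(mv$ratio, c(0.5, NA))
  expect_identical(mv$exceeds_flag, c(0L, 1L))
})

test_that("intercept-only negative binomial recovers the sample mean", {
  set.seed(81)
  y <- rnbinom(400, size = 2, mu = 5)
  res <- fit_negbin_visits(y, cbind(dummy = rbinom(400, 1, 0.5)))
  ic <- res[res$term == "(Intercept)", ]
  expect_gt(exp(ic$estimate + 2 * ic$std_error), 5)
  expect_lt(exp(ic$estimate - 2 * ic$std_error), 5)
  expect_gt(res$dispersion[1], 0)
  expect_true(all(res$ci_low < res$effect & res$effect < res$ci_high))
  expect_error(fit_negbin_visits(c(-1, 2), cbind(x = c(0, 1))), "non-negative")
  expect_error(fit_negbin_visits(c(1, 2, 3), cbind(a = c(1, 1, 1))),
               "rank deficient")
})

test_that("negative binomial Wald CI covers a generator IRR", {
  hits <- 0L
  for (i in seq_len(50)) {
    set.seed(900 + i)
    x <- rbinom(500, 1, 0.5)
    y <- rnbinom(500, size = 1.5, mu = 4 * 3^x)   # IRR 3.0
    res <- fit_negbin_visits(y, cbind(grp = x))
    row <- res[res$term == "grp", ]
    hits <- hits + (row$ci_low <= 3 && 3 <= row$ci_high)
  }
  expect_gte(hits, 45L)
})

test_that("equidispersed counts agree with a Poisson oracle fit", {
  set.seed(83)
  x <- rbinom(800, 1, 0.5)
  y <- rpois(800, lambda = 3 * 2^x)
  nb <- fit_negbin_visits(y, cbind(grp = x))
  pois <- glm(y ~ x, family = poisson())
  row <- nb[nb$term == "grp", ]
  expect_lt(abs(row$estimate - coef(pois)[["x"]]), row$std_error)
})

test_that("logistic regression recovers ORs and detects separation", {
  set.seed(84)
  y <- rbinom(600, 1, 0.5)
  res <- fit_logistic_structure(y, cbind(noise = rnorm(600)))
  ic <- res[res$term == "(Intercept)", ]
  expect_lt(abs(ic$estimate), 3 * ic$std_error)   # balanced outcome: OR ~ 1

  hits <- 0L
  for (i in seq_len(50)) {
    set.seed(2000 + i)
    x <- rbinom(780, 1, 0.5)
    pr <- plogis(qlogis(0.6) + log(0.41) * x)
    yy <- rbinom(780, 1, pr)
    r <- fit_logistic_structure(yy, cbind(muni = x))
    row <- r[r$term == "muni", ]
    hits <- hits + (row$ci_low <= 0.41 && 0.41 <= row$ci_high)
  }
  expect_gte(hits, 45L)

  sep_x <- c(rep(0, 50), rep(1, 50))
  sep_y <- sep_x
  expect_error(fit_logistic_structure(sep_y, cbind(leak = sep_x)),
               "separation in .*leak")
})

test_that("effects render in the report style", {
  row <- data.frame(effect_type = "IRR", effect = 3.02,
                    ci_low = 2.42, ci_high = 3.77)
  expect_identical(format_glm_effect(row), "IRR 3.02, 95% CI 2.42–3.77")
  row2 <- data.frame(effect_type = "OR", effect = 0.41,
                     ci_low = 0.27, ci_high = 0.61)
  expect_identical(format_glm_effect(row2), "OR 0.41, 95% CI 0.27–0.61")
})
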