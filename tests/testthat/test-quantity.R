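test_that("standardize_covariates is an exact affine normalization", {
  df <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  std <- standardize_covariates(df, "a")
  expect_equal(mean(std$matrix[, "a"]), 0)
  expect_equal(sd(std$matrix[, "a"]), 1)
  expect_equal(std$scale_record$sd, 1)
  expect_error(standardize_covariates(df, "b"), "zero variance")
  expect_error(standardize_covariates(df, "c"), "no column")
  expect_error(standardize_covariates(df[1, , drop = FALSE], "a"),
               "at least 2")
  # the scale record carries original units for per-1-SD reporting
  df2 <- data.frame(visits = c(0, 2, 13, 6.56 * 2, 1, 7))
  s2 <- standardize_covariates(df2, "visits")
  expect_equal(s2$scale_record$sd, sd(df2$visits))
})

test_that("design-matrix codings match the study's variable table", {
  rec <- data.frame(
    municipality = c("manaus", "carauari"),
    residence_status = c("multisited", "single_sited"),
    urbanization = c("rural", "urban"),
    season = c("dry", "wet"), stringsAsFactors = FALSE)
  X <- quantity_design_matrix(rec)$matrix
  expect_identical(X[1, ], c(municipality_manaus = 1L,
                             residence_multisited = 1L,
                             urbanization_rural = 1L,
                             urbanization_peri_urban = 0L,
                             season_dry = 1L))
  # reference levels: Carauari, single-sited, urban, wet -> all zeros
  expect_identical(unname(X[2, ]), rep(0L, 5))
})

test_that("unmasked fit reduces to the frequentist proportional-odds fit", {
  set.seed(71)
  n <- 600
  X <- cbind(b1 = rbinom(n, 1, 0.5), x2 = rnorm(n))
  qcat <- make_ordinal_sample(X, c(log(2), log(1.5)), c(-1, 0, 1, 2))
  spec <- quantity_model_spec(1, rep(0.2, 5))
  fit <- fit_quantity_model(qcat, X, spec, mcmc_config(1200, 1500, 2, seed = 4))
  post_mean <- apply(fit$beta, 2, mean)
  post_sd <- apply(fit$beta, 2, sd)
  oracle <- MASS::polr(factor(qcat, ordered = TRUE) ~ X, method = "logistic")
  expect_true(all(abs(post_mean - coef(oracle)) < 2 * post_sd))
  # cutpoints too
  kappa_mean <- apply(fit$kappa, 2, mean)
  expect_lt(max(abs(kappa_mean - oracle$zeta)), 0.3)
})

test_that("null coefficients are recovered as null", {
  set.seed(72)
  n <- 500
  X <- cbind(b1 = rbinom(n, 1, 0.5))
  qcat <- make_ordinal_sample(X, 0, c(-0.5, 0.5, 1.5))
  spec <- quantity_model_spec(1, rep(0.25, 4))
  fit <- fit_quantity_model(qcat, X, spec, mcmc_config(1000, 1200, 2, seed = 5))
  ci <- quantile(fit$beta[, 1, ], c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
  tab <- odds_ratio_summary(fit)
  expect_lt(tab$cri_low, 1)   # OR interval straddles 1
  expect_gt(tab$cri_high, 1)
})

test_that("masked ordinal fit recovers generator effects", {
  set.seed(73)
  n <- 900
  X <- cbind(b1 = rbinom(n, 1, 0.5))
  qcat <- make_ordinal_sample(X, log(2.5), c(-1, 0, 1, 2))
  ns_probs <- c(0.5, 0.2, 0.15, 0.1, 0.05)
  obs <- mask_ordinal(qcat, ns_probs, 2 / 3)
  spec <- quantity_model_spec(2 / 3, ns_probs)
  fit <- fit_quantity_model(obs, X, spec, mcmc_config(1500, 2000, 2, seed = 6))
  ci <- quantile(fit$beta[, 1, ], c(0.025, 0.975))
  expect_lt(ci[1], log(2.5))
  expect_gt(ci[2], log(2.5))
  expect_lt(abs(mean(fit$beta[, 1, ]) - log(2.5)), 0.35)
})

test_that("category probabilities are a simplex, monotone in the predictor", {
  set.seed(74)
  X <- matrix(rnorm(20), 10, 2)
  beta <- c(0.5, -0.3)
  kappa <- c(-1, 0.2, 1.4)
  pr <- predict_category_probs(beta, kappa, X)
  expect_equal(rowSums(pr), rep(1, 10), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  # cumulative P(cat <= k) decreases as the linear predictor grows
  eta <- seq(-2, 2, length.out = 9)
  Xe <- cbind(eta)
  pre <- predict_category_probs(1, kappa, Xe)
  cum1 <- t(apply(pre, 1, cumsum))[, 1:3]
  expect_true(all(diff(cum1[, 1]) < 0))
  expect_true(all(apply(cum1, 2, function(col) all(diff(col) <= 1e-12))))
})

test_that("odds-ratio table matches lognormal closed forms", {
  draws <- matrix(rep(log(2), 400), ncol = 2)
  tab <- odds_ratio_summary(array(draws, c(200, 1, 2),
                                  dimnames = list(NULL, "b", NULL)))
  expect_equal(tab$or, 2)
  expect_equal(tab$cri_low, 2)
  expect_equal(tab$cri_high, 2)

  set.seed(75)
  d2 <- array(rnorm(40000, 0.5, 0.1), c(20000, 1, 2),
              dimnames = list(NULL, "visits", NULL))
  sr <- data.frame(covariate = "visits", mean = 10, sd = 6.56)
  tab2 <- odds_ratio_summary(d2, sr)
  expect_lt(abs(tab2$or - exp(0.5)), 0.02)
  expect_lt(abs(tab2$cri_low - exp(0.5 - 1.96 * 0.1)), 0.02)
  expect_lt(abs(tab2$cri_high - exp(0.5 + 1.96 * 0.1)), 0.02)
  expect_identical(tab2$scale_note, "per 1 SD (= 6.56 visits)")
})

test_that("spec guards reject malformed inputs", {
  expect_error(quantity_model_spec(0, rep(0.25, 4)), "p_s")
  expect_error(quantity_model_spec(0.5, c(0.5, 0.6)), "probability vector")
  spec <- quantity_model_spec(1, rep(0.25, 4))
  expect_error(fit_quantity_model(c(0, 5), cbind(1, 0), spec,
                                  mcmc_config(10, 10, 1, seed = 1)),
               "0..K")
})
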