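test_that("mom_estimate inverts the mixture identity and flags clipping", {
  expect_equal(mom_estimate(0.3, 1, 0.5)$estimate, 0.3)   # direct-question limit
  # boundary: p_obs exactly the unrelated-only rate
  p_s <- 2 / 3
  pi_ns <- 0.4
  b <- mom_estimate((1 - p_s) * pi_ns, p_s, pi_ns)
  expect_equal(b$estimate, 0)
  expect_false(b$clipped)
  low <- mom_estimate(0.05, p_s, pi_ns)
  expect_identical(low$estimate, 0)
  expect_true(low$clipped)
  expect_lt(low$raw, 0)
  expect_error(mom_estimate(0.5, 0, 0.4), "p_s = 0")
})

test_that("mom_estimate agrees with a Monte-Carlo reinversion oracle", {
  p_s <- 2 / 3
  pi_ns <- 0.4
  est <- mom_estimate(0.6, p_s, pi_ns)$estimate   # implied pi_s = 0.7
  y <- make_masked_sample(1e6, est, pi_ns, p_s, seed = 77)
  est_back <- mom_estimate(mean(y), p_s, pi_ns)$estimate
  expect_lt(abs(est_back - est), 0.005)
  expect_equal(est, 0.7, tolerance = 1e-12)
})

test_that("grid oracle recovers conjugate closed forms and normalizes", {
  spec1 <- mixture_model_spec(1, "known", pi_ns_value = 0)
  # no data, flat prior -> prior recovery
  g0 <- grid_posterior_oracle(integer(0), spec1)
  expect_equal(g0$mean, 0.5, tolerance = 1e-6)
  # 7 of 10 ones, Beta(1,1) -> Beta(8,4), mean 8/12
  g <- grid_posterior_oracle(c(rep(1, 7), rep(0, 3)), spec1)
  expect_equal(g$mean, 8 / 12, tolerance = 1e-4)
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  expect_equal(g$cri_low, qbeta(0.025, 8, 4), tolerance = 2e-3)
  expect_equal(g$cri_high, qbeta(0.975, 8, 4), tolerance = 2e-3)
  expect_error(grid_posterior_oracle(c(0, 1), spec1, grid_size = 20),
               "resolution floor")
})

test_that("Gibbs sampler matches conjugate posteriors when masking is off", {
  spec <- mixture_model_spec(1, "known", pi_ns_value = 0)
  y <- c(rep(1L, 30), rep(0L, 70))
  fit <- fit_prevalence_gibbs(y, spec, mcmc_config(500, 4000, 2, seed = 9))
  expect_equal(mean(fit$pi_s), 31 / 102, tolerance = 0.01)    # Beta(31,71)
  expect_equal(sd(as.vector(fit$pi_s)), sqrt(31 * 71 / (102^2 * 103)),
               tolerance = 0.02)
})

test_that("all-zero data with known pi_ns = 0 concentrates near zero", {
  spec <- mixture_model_spec(2 / 3, "known", pi_ns_value = 0)
  fit <- fit_prevalence_gibbs(rep(0L, 200), spec,
                              mcmc_config(500, 3000, 2, seed = 13))
  expect_lt(mean(fit$pi_s), 0.05)
})

test_that("Gibbs and grid oracle agree on masked data", {
  spec <- mixture_model_spec(2 / 3, "known", pi_ns_value = 0.2)
  y <- make_masked_sample(300, 0.5, 0.2, 2 / 3, seed = 41)
  fit <- fit_prevalence_gibbs(y, spec, mcmc_config(1000, 5000, 2, seed = 42))
  g <- grid_posterior_oracle(y, spec)
  s <- summarize_posterior(fit$pi_s)
  expect_lt(abs(s$mean - g$mean), 0.01)
  expect_lt(abs(s$cri_low - g$cri_low), 0.02)
  expect_lt(abs(s$cri_high - g$cri_high), 0.02)
})

test_that("masking loses information monotonically (interval width)", {
  set.seed(55)
  latent <- rbinom(300, 1, 0.5)
  spec_direct <- mixture_model_spec(1, "known", pi_ns_value = 0.3)
  # mask the same latent uses through the domino draw
  z <- rbinom(300, 1, 2 / 3)
  y_masked <- ifelse(z == 1, latent, rbinom(300, 1, 0.3))
  spec_masked <- mixture_model_spec(2 / 3, "known", pi_ns_value = 0.3)
  g1 <- grid_posterior_oracle(latent, spec_direct)
  g2 <- grid_posterior_oracle(y_masked, spec_masked)
  expect_gte(g2$cri_high - g2$cri_low, g1$cri_high - g1$cri_low)
})

test_that("method-of-moments is consistent over replicates", {
  p_s <- 2 / 3
  pi_ns <- 0.3
  pi_s <- 0.5
  ests <- vapply(seq_len(500), function(i) {
    y <- make_masked_sample(2000, pi_s, pi_ns, p_s, seed = 7000 + i)
    mom_estimate(mean(y), p_s, pi_ns)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - pi_s), 0.01)
})

test_that("beta_prior mode warns about the identifiability ridge", {
  expect_warning(spec <- mixture_model_spec(2 / 3, "beta_prior"),
                 "not jointly identified")
  y <- make_masked_sample(400, 0.6, 0.3, 2 / 3, seed = 8)
  g_ridge <- grid_posterior_oracle(y, spec, grid_size = 400)
  known <- mixture_model_spec(2 / 3, "known", pi_ns_value = 0.3)
  g_known <- grid_posterior_oracle(y, known, grid_size = 400)
  sd_of <- function(g) sqrt(sum(g$mass * (g$grid - g$mean)^2))
  # the ridge inflates the marginal posterior spread well beyond known mode
  expect_gt(sd_of(g_ridge), 1.5 * sd_of(g_known))
  # and the Gibbs sampler runs in this mode, returning pi_ns draws too
  fit <- fit_prevalence_gibbs(y, spec, mcmc_config(500, 1000, 2, seed = 3))
  expect_false(is.null(fit$pi_ns))
})

test_that("per-cell driver estimates every observed cell reproducibly", {
  d <- tiny_design(15L)
  p <- default_true_params(d)
  hh <- simulate_households(d, p, seed = 61)
  r <- simulate_responses(hh, p, d, seed = 62)
  sub <- r$analysis[r$analysis$item_domain == "chelonians:consumption", ]
  mc <- mcmc_config(300, 400, 2, seed = 17)
  cells <- fit_prevalence_cells(sub, p_s = 2 / 3, pi_ns = 0.5, mcmc = mc)
  expect_identical(nrow(cells), 12L)   # 2 muni x 3 urb x 2 seasons
  expect_true(all(cells$cri_low <= cells$median &
                    cells$median <= cells$cri_high))
  expect_true(all(cells$mean >= 0 & cells$mean <= 1))
  cells2 <- fit_prevalence_cells(sub, p_s = 2 / 3, pi_ns = 0.5, mcmc = mc)
  expect_equal(cells$mean, cells2$mean)   # hashed per-cell seeds
  expect_warning(empty <- fit_prevalence_cells(sub[0, ], 2 / 3, 0.5, mc),
                 "no responses")
  expect_identical(nrow(empty), 0L)
})
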