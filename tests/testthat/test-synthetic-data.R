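test_that("simulate_households matches the design exactly and is seeded", {
  d <- study_design()
  p <- default_true_params(d)
  hh <- simulate_households(d, p, seed = 11)
  expect_identical(nrow(hh), 782L)
  expect_identical(sum(hh$municipality == "manaus"), 509L)
  counts <- table(hh$municipality, hh$urbanization)
  expect_identical(unname(counts["manaus", "urban"]), 299L)
  expect_identical(unname(counts["carauari", "peri_urban"]), 41L)
  # determinism under a fixed seed; seed is mandatory
  expect_identical(hh, simulate_households(d, p, seed = 11))
  expect_false(identical(hh, simulate_households(d, p, seed = 12)))
  expect_error(simulate_households(d, p), "seed")
  # exactly one visits column applicable per household
  urban <- hh$urbanization == "urban"
  expect_true(all(is.na(hh$visits_urban[urban])))
  expect_true(all(!is.na(hh$visits_rural[urban])))
  expect_true(all(!is.na(hh$visits_urban[!urban])))
  expect_true(all(is.na(hh$visits_rural[!urban])))
})

test_that("generator marginals approximate the stated world", {
  d <- study_design()
  p <- default_true_params(d)
  stats <- vapply(1:8, function(i) {
    hh <- simulate_households(d, p, seed = 1000 + i)
    c(multi = mean(hh$residence_status == "multisited"),
      sd_vu = sd(hh$visits_urban, na.rm = TRUE),
      sd_vr = sd(hh$visits_rural, na.rm = TRUE))
  }, numeric(3))
  m <- rowMeans(stats)
  expect_lt(abs(m["multi"] - 0.19), 0.03)      # ~19% multisited
  expect_lt(abs(m["sd_vu"] - 21.76) / 21.76, 0.30)
  expect_lt(abs(m["sd_vr"] - 6.56) / 6.56, 0.30)
})

test_that("masked responses obey the mixture identity per cell", {
  # one large stratum so the per-cell empirical rate is tight
  st <- data.frame(municipality = "manaus", urbanization = "urban",
                   n_households = 15000L)
  d <- study_design(strata = st, seasons = "dry",
                    item_domains = "chelonians:consumption")
  p <- default_true_params(d)
  p$pi_s <- data.frame(municipality = "manaus", urbanization = "urban",
                       item_domain = "chelonians:consumption",
                       season = "dry", pi = 0.6)
  p$pi_ns[] <- 0.3
  hh <- simulate_households(d, p, seed = 5)
  r <- simulate_responses(hh, p, d, seed = 6)
  n <- nrow(r$analysis)
  expect_identical(n, 15000L)
  expected <- 2 / 3 * 0.6 + 1 / 3 * 0.3
  band <- qbinom(c(0.005, 0.995), n, expected)  # exact binomial oracle
  expect_gte(sum(r$analysis$use), band[1])
  expect_lte(sum(r$analysis$use), band[2])
})

test_that("saturated prevalences give universal observed use", {
  d <- tiny_design(5L)
  p <- default_true_params(d)
  p$pi_s$pi <- 1
  p$pi_ns[] <- 1
  hh <- simulate_households(d, p, seed = 2)
  r <- simulate_responses(hh, p, d, seed = 3)
  expect_true(all(r$analysis$use == 1L))
  expect_true(all(r$analysis$quantity_category >= 1L))
})

test_that("dry-over-wet prevalence ordering survives masking", {
  st <- data.frame(municipality = "carauari", urbanization = "rural",
                   n_households = 5000L)
  d <- study_design(strata = st, item_domains = "mammals_birds:consumption")
  p <- default_true_params(d)
  p$pi_s <- data.frame(
    municipality = "carauari", urbanization = "rural",
    item_domain = "mammals_birds:consumption",
    season = c("dry", "wet"), pi = c(0.7, 0.4))
  for (seed in c(21, 22, 23)) {
    hh <- simulate_households(d, p, seed = seed)
    r <- simulate_responses(hh, p, d, seed = seed + 100)
    rate <- tapply(r$analysis$use, r$analysis$season, mean)
    expect_gt(rate[["dry"]], rate[["wet"]])
  }
})

test_that("truth/analysis split hides the latent assignment", {
  d <- tiny_design(6L)
  p <- default_true_params(d)
  hh <- simulate_households(d, p, seed = 4)
  r <- simulate_responses(hh, p, d, seed = 5)
  expect_true(all(c("z", "latent_use") %in% names(r$truth)))
  expect_false(any(c("z", "latent_use") %in% names(r$analysis)))
  # quantity_category = 0 iff use = 0
  expect_identical(r$analysis$quantity_category == 0L, r$analysis$use == 0L)
  # identical seeds give identical tables
  r2 <- simulate_responses(hh, p, d, seed = 5)
  expect_identical(r, r2)
  # unknown stratum cell errors
  p2 <- p
  p2$pi_s <- p2$pi_s[p2$pi_s$municipality != "manaus", ]
  expect_error(simulate_responses(hh, p2, d, seed = 5), "no pi_s entry")
})
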