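# Shared fixtures: all synthetic, built in code at test time.

# Masked binary responses for one cell under the unrelated-question design.
make_masked_sample <- function(n, pi_s, pi_ns, p_s, seed) {
  set.seed(seed)
  z <- stats::rbinom(n, 1L, p_s)
  ifelse(z == 1L,
         stats::rbinom(n, 1L, pi_s),
         stats::rbinom(n, 1L, pi_ns))
}

# Ordinal categories 0..K straight from the proportional-odds model.
make_ordinal_sample <- function(X, beta, kappa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- as.vector(as.matrix(X) %*% beta)
  cum <- vapply(kappa, function(k) stats::plogis(k - eta),
                numeric(length(eta)))
  rowSums(stats::runif(length(eta)) > cum)
}

# Mask proportional-odds categories through the unrelated branch.
mask_ordinal <- function(qcat, ns_cat_probs, p_s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(qcat)
  z <- stats::rbinom(n, 1L, p_s)
  ns <- sample(seq_along(ns_cat_probs) - 1L, n, TRUE, ns_cat_probs)
  ifelse(z == 1L, qcat, ns)
}

# A small but full-rank study design: all six strata, few households each.
tiny_design <- function(n_per_stratum = 10L) {
  st <- default_strata()
  st$n_households <- n_per_stratum
  study_design(strata = st)
}

write_tiny_pipeline_config <- function(path, workdir, seed = 7L,
                                       n_per_stratum = 10L,
                                       n_burnin = 300L, n_samples = 300L) {
  writeLines(c(
    sprintf("seed: %d", seed),
    sprintf("workdir: %s", workdir),
    "generator:",
    "  design:",
    "    strata:",
    sprintf("      - {municipality: %s, urbanization: %s, n_households: %d}",
            rep(c("manaus", "carauari"), each = 3L),
            rep(c("rural", "peri_urban", "urban"), 2L), n_per_stratum),
    sprintf("mcmc: {n_burnin: %d, n_samples: %d, n_chains: 2}",
            n_burnin, n_samples),
    "models:",
    "  prevalence: [\"chelonians:consumption\"]",
    "  quantity:",
    "    - {item_domain: \"chelonians:consumption\"}",
    "  glms: [dual_adult, dependency]"
  ), path)
  path
}
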