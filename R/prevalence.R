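# Prevalence of the sensitive behaviour from masked binary responses.
#
# Observation model: the respondent answers the sensitive question with
# probability p_s (the domino draw), else an unrelated question with
# prevalence pi_ns, so P(y = 1) = p_s * pi_s + (1 - p_s) * pi_ns.
# Inference is by data augmentation: conditional on pi_s the latent
# assignment z_i is Bernoulli, and conditional on z the Beta prior on pi_s
# is conjugate. Because P(z_i = sensitive | y_i) depends on y_i only, the
# augmentation collapses to two binomial draws per sweep, making the
# sampler O(1) per iteration regardless of cell size.

#' Mixture model specification for masked prevalence
#'
#' @param p_s Probability the randomizer selects the sensitive question
#'   (in `(0, 1]`).
#' @param pi_ns_mode `"known"` (default; the unrelated-item prevalence is a
#'   fixed design quantity) or `"beta_prior"` (estimate it, with a
#'   documented identifiability caveat: a single-sample unrelated-question
#'   design cannot separate `pi_s` from `pi_ns` using binary responses
#'   alone, so the posterior has a ridge and leans on the priors).
#' @param pi_ns_value Known unrelated-item prevalence (required in known
#'   mode).
#' @param pi_s_prior,pi_ns_prior Beta hyperparameters `c(a, b)`, both > 0.
#' @return Object of class `mixture_model_spec`.
#' @export
mixture_model_spec <- function(p_s, pi_ns_mode = c("known", "beta_prior"),
                               pi_ns_value = NULL,
                               pi_s_prior = c(1, 1), pi_ns_prior = c(1, 1)) {
  pi_ns_mode <- match.arg(pi_ns_mode)
  if (length(p_s) != 1L || is.na(p_s) || p_s <= 0 || p_s > 1)
    stop("mixture_model_spec: p_s must lie in (0, 1]", call. = FALSE)
  if (any(pi_s_prior <= 0) || any(pi_ns_prior <= 0))
    stop("mixture_model_spec: Beta hyperparameters must be positive",
         call. = FALSE)
  if (pi_ns_mode == "known") {
    if (is.null(pi_ns_value) || is.na(pi_ns_value) ||
        pi_ns_value < 0 || pi_ns_value > 1)
      stop("mixture_model_spec: known mode requires pi_ns_value in [0, 1]",
           call. = FALSE)
  } else {
    warning("mixture_model_spec: beta_prior mode -- pi_s and pi_ns are not ",
            "jointly identified from binary responses in a single-sample ",
            "design; the posterior has a ridge and the priors matter",
            call. = FALSE)
  }
  structure(
    list(p_s = p_s, pi_ns_mode = pi_ns_mode, pi_ns_value = pi_ns_value,
         pi_s_prior = pi_s_prior, pi_ns_prior = pi_ns_prior),
    class = "mixture_model_spec"
  )
}

#' MCMC configuration
#'
#' Defaults follow the study's reported settings: 50,000 burn-in iterations
#' discarded and 25,000 retained posterior samples.
#'
#' @param n_burnin,n_samples,n_chains,thin Positive integers.
#' @param seed Integer master seed for the sampler.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = 50000L, n_samples = 25000L,
                        n_chains = 2L, thin = 1L, seed = 1L) {
  v <- c(n_burnin = n_burnin, n_samples = n_samples,
         n_chains = n_chains, thin = thin)
  if (any(is.na(v)) || any(v < 1))
    stop("mcmc_config: all settings must be positive integers", call. = FALSE)
  structure(list(n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 n_chains = as.integer(n_chains),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Method-of-moments prevalence estimate
#'
#' Inverts the mixture identity `p_obs = p_s * pi_s + (1 - p_s) * pi_ns`
#' for the sensitive prevalence. Estimates falling outside `[0, 1]` (which
#' is expected at small n) are clipped and flagged, not treated as errors.
#'
#' @param p_obs Observed masked-use proportion in `[0, 1]`.
#' @param p_s Sensitive-question probability (> 0).
#' @param pi_ns Known unrelated-item prevalence.
#' @return Object of class `mom_estimate`: list with `estimate` (clipped to
#'   `[0, 1]`), `raw`, and logical `clipped`.
#' @export
mom_estimate <- function(p_obs, p_s, pi_ns) {
  if (p_s == 0)
    stop("mom_estimate: p_s = 0 carries no information about pi_s",
         call. = FALSE)
  if (p_obs < 0 || p_obs > 1)
    stop("mom_estimate: p_obs must lie in [0, 1]", call. = FALSE)
  raw <- (p_obs - (1 - p_s) * pi_ns) / p_s
  est <- min(max(raw, 0), 1)
  structure(list(estimate = est, raw = raw, clipped = !identical(raw, est)),
            class = "mom_estimate")
}

#' Gibbs sampler for masked prevalence in one cell
#'
#' Data-augmentation Gibbs sampler. Each sweep (i) draws the latent counts
#' of sensitive-question assignments among the `y = 1` and `y = 0`
#' respondents from their conditional binomials, then (ii) draws `pi_s`
#' from its conjugate Beta given those counts; in `beta_prior` mode (iii)
#' draws `pi_ns` analogously from the complementary counts.
#'
#' @param y Integer/binary vector of masked responses for one
#'   stratum x item-domain x season cell.
#' @param spec A [mixture_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @return Object of class `prevalence_fit`: list with `pi_s` (matrix,
#'   `n_samples` x `n_chains`), `pi_ns` (same shape, or `NULL` in known
#'   mode), `n`, `spec`, `mcmc`.
#' @export
fit_prevalence_gibbs <- function(y, spec, mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "mixture_model_spec"), inherits(mcmc, "mcmc_config"))
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L)))
    stop("fit_prevalence_gibbs: responses must be binary", call. = FALSE)
  n1 <- sum(y)
  n0 <- length(y) - n1
  p_s <- spec$p_s
  a_s <- spec$pi_s_prior[1L]; b_s <- spec$pi_s_prior[2L]
  known <- spec$pi_ns_mode == "known"
  a_n <- spec$pi_ns_prior[1L]; b_n <- spec$pi_ns_prior[2L]

  n_keep <- mcmc$n_samples
  total <- mcmc$n_burnin + n_keep * mcmc$thin
  eps <- 1e-300
  draws_s <- matrix(NA_real_, n_keep, mcmc$n_chains)
  draws_n <- if (known) NULL else matrix(NA_real_, n_keep, mcmc$n_chains)

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, paste0("prevalence-chain-", ch)))
    pi_s <- stats::rbeta(1L, a_s, b_s)
    pi_ns <- if (known) spec$pi_ns_value else stats::rbeta(1L, a_n, b_n)
    kept <- 0L
    for (it in seq_len(total)) {
      q1 <- (p_s * pi_s) / (p_s * pi_s + (1 - p_s) * pi_ns + eps)
      q0 <- (p_s * (1 - pi_s)) /
        (p_s * (1 - pi_s) + (1 - p_s) * (1 - pi_ns) + eps)
      s1 <- stats::rbinom(1L, n1, q1)   # sensitive-assigned among y = 1
      s0 <- stats::rbinom(1L, n0, q0)   # sensitive-assigned among y = 0
      pi_s <- stats::rbeta(1L, a_s + s1, b_s + s0)
      if (!known)
        pi_ns <- stats::rbeta(1L, a_n + (n1 - s1), b_n + (n0 - s0))
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        draws_s[kept, ch] <- pi_s
        if (!known) draws_n[kept, ch] <- pi_ns
      }
    }
  }
  structure(list(pi_s = draws_s, pi_ns = draws_n, n = length(y),
                 spec = spec, mcmc = mcmc),
            class = "prevalence_fit")
}

#' Exact grid posterior for masked prevalence (verification oracle)
#'
#' Evaluates the exact marginal likelihood
#' `prod_i [p_s Bern(y_i; pi_s) + (1 - p_s) Bern(y_i; pi_ns)]` times the
#' priors on a uniform grid and normalizes. In known mode this is a 1-D
#' grid over `pi_s`; in `beta_prior` mode a 2-D grid with `pi_ns`
#' marginalized out. Independent of the Gibbs code path by construction:
#' no latent variables, no MCMC.
#'
#' @inheritParams fit_prevalence_gibbs
#' @param grid_size Number of grid points per dimension (>= 50).
#' @return Object of class `grid_posterior`: list with `grid` (midpoints),
#'   `mass` (sums to 1), `mean`, `cri_low`, `cri_high`, `median`.
#' @export
grid_posterior_oracle <- function(y, spec, grid_size = 2000L) {
  stopifnot(inherits(spec, "mixture_model_spec"))
  if (grid_size < 50L)
    stop("grid_posterior_oracle: grid_size below the resolution floor of 50",
         call. = FALSE)
  y <- as.integer(y)
  n1 <- sum(y)
  n0 <- length(y) - n1
  p_s <- spec$p_s
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  loglik_at <- function(pi_s, pi_ns) {
    p <- p_s * pi_s + (1 - p_s) * pi_ns
    n1 * log(p) + n0 * log1p(-p)
  }
  if (spec$pi_ns_mode == "known") {
    ll <- loglik_at(grid, spec$pi_ns_value) +
      stats::dbeta(grid, spec$pi_s_prior[1L], spec$pi_s_prior[2L], log = TRUE)
  } else {
    lp_ns <- stats::dbeta(grid, spec$pi_ns_prior[1L], spec$pi_ns_prior[2L],
                          log = TRUE)
    ll <- vapply(grid, function(ps) {
      v <- loglik_at(ps, grid) + lp_ns
      mx <- max(v)
      mx + log(sum(exp(v - mx)))
    }, numeric(1L)) +
      stats::dbeta(grid, spec$pi_s_prior[1L], spec$pi_s_prior[2L], log = TRUE)
  }
  ll[!is.finite(ll)] <- -Inf
  mass <- exp(ll - max(ll))
  mass <- mass / sum(mass)
  cum <- cumsum(mass)
  qat <- function(p) grid[which(cum >= p)[1L]]
  structure(list(grid = grid, mass = mass,
                 mean = sum(grid * mass),
                 median = qat(0.5), cri_low = qat(0.025),
                 cri_high = qat(0.975)),
            class = "grid_posterior")
}

#' Estimate prevalence for every cell of an analysis table
#'
#' Groups the analysis-facing responses by municipality x urbanization x
#' item domain x season and runs the Gibbs sampler per cell, with the
#' per-cell seed derived from the MCMC seed by stable hashing of the cell
#' key (so cells are reproducible in any execution order). Cells without
#' any responses are skipped with a warning, never a crash.
#'
#' @param responses Analysis-facing data frame ([read_survey_csv()] schema).
#' @param p_s Randomizer sensitive-question probability.
#' @param pi_ns Known unrelated-item prevalence: scalar, or named vector by
#'   item domain.
#' @param mcmc An [mcmc_config()].
#' @param pi_s_prior Beta hyperparameters for every cell.
#' @return Data frame, one row per cell: cell keys, `n_households`, `mean`,
#'   `median`, `cri_low`, `cri_high`, `rhat`, `ess`; the matrix of draws for
#'   each cell is attached as attribute `"draws"` (a named list).
#' @export
fit_prevalence_cells <- function(responses, p_s, pi_ns,
                                 mcmc = mcmc_config(), pi_s_prior = c(1, 1)) {
  key <- interaction(responses$municipality, responses$urbanization,
                     responses$item_domain, responses$season,
                     sep = "|", drop = TRUE)
  cells <- split(responses, key)
  if (length(cells) == 0L) {
    warning("fit_prevalence_cells: no responses; nothing to estimate",
            call. = FALSE)
    return(data.frame())
  }
  out <- vector("list", length(cells))
  draws <- vector("list", length(cells))
  names(draws) <- names(cells)
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    parts <- strsplit(names(cells)[i], "|", fixed = TRUE)[[1L]]
    if (nrow(cell) == 0L) {
      warning("fit_prevalence_cells: empty cell skipped: ", names(cells)[i],
              call. = FALSE)
      next
    }
    pi_ns_cell <- if (length(pi_ns) == 1L) unname(pi_ns) else
      unname(pi_ns[[cell$item_domain[1L]]])
    spec <- mixture_model_spec(p_s, "known", pi_ns_value = pi_ns_cell,
                               pi_s_prior = pi_s_prior)
    cell_mcmc <- mcmc
    cell_mcmc$seed <- derive_seed(mcmc$seed, names(cells)[i])
    fit <- fit_prevalence_gibbs(cell$use, spec, cell_mcmc)
    s <- summarize_posterior(fit$pi_s)
    draws[[i]] <- fit$pi_s
    out[[i]] <- data.frame(
      municipality = parts[1L], urbanization = parts[2L],
      item_domain = parts[3L], season = parts[4L],
      n_households = nrow(cell),
      mean = s$mean, median = s$median,
      cri_low = s$cri_low, cri_high = s$cri_high,
      rhat = s$rhat, ess = s$ess, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- draws
  res
}
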