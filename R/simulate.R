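# Synthetic survey generator: households with covariates, then masked
# responses under the domino randomizer.

#' Simulate household records
#'
#' Draws one record per designed household. Per-stratum counts match the
#' design exactly (not in expectation). Covariates are drawn from
#' stratum-specific distributions parameterized by `params$glm_betas`:
#' residence status and household management are Bernoulli with
#' stratum-specific probabilities; minors are Poisson and working adults
#' `1 + Poisson` (so the dependency denominator is rarely zero); visit
#' counts are negative binomial with multiplicative incidence-rate effects.
#' Rural and peri-urban households report visits to the urban centre,
#' urban households report visits to rural areas; the inapplicable count is
#' `NA`, never a silent zero.
#'
#' @param design A validated [study_design()].
#' @param params A [true_params()].
#' @param seed Integer seed; mandatory (all simulation is explicitly seeded).
#' @return Data frame of household records, one row per household.
#' @export
simulate_households <- function(design, params, seed) {
  if (missing(seed) || is.null(seed))
    stop("simulate_households: 'seed' is required", call. = FALSE)
  validate_design(design)
  gb <- params$glm_betas
  set.seed(seed)

  pieces <- vector("list", nrow(design$strata))
  for (i in seq_len(nrow(design$strata))) {
    muni <- design$strata$municipality[i]
    urb <- design$strata$urbanization[i]
    n <- design$strata$n_households[i]
    manaus <- as.integer(muni == "manaus")

    multisited <- stats::rbinom(n, 1L, gb$multisited_prob[[urb]])
    da <- gb$dual_adult
    p_dual <- stats::plogis(stats::qlogis(da$p0) +
                              log(da$or_manaus) * manaus +
                              log(da$or_rural) * (urb == "rural") +
                              log(da$or_peri_urban) * (urb == "peri_urban"))
    dual <- stats::rbinom(n, 1L, p_dual)
    n_minors <- stats::rpois(n, gb$minors_lambda)
    n_working <- 1L + stats::rpois(n, gb$working_lambda)

    if (urb %in% c("rural", "peri_urban")) {
      vu <- gb$visits_urban
      mu <- vu$mu0 * vu$irr_manaus^manaus *
        vu$irr_peri_urban^(urb == "peri_urban")
      visits_urban <- stats::rnbinom(n, size = vu$size, mu = mu)
      visits_rural <- rep(NA_integer_, n)
    } else {
      vr <- gb$visits_rural
      mu <- vr$mu0 * vr$irr_manaus^manaus * vr$irr_multisited^multisited
      visits_rural <- stats::rnbinom(n, size = vr$size, mu = mu)
      visits_urban <- rep(NA_integer_, n)
    }

    pieces[[i]] <- data.frame(
      household_id = sprintf("%s_%s_%04d", muni, urb, seq_len(n)),
      municipality = muni,
      urbanization = urb,
      residence_status = c("single_sited", "multisited")[multisited + 1L],
      management = c("single_adult", "dual_adult")[dual + 1L],
      n_minors = n_minors,
      n_working_adults = n_working,
      visits_urban = visits_urban,
      visits_rural = visits_rural,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, pieces)
}

#' Simulate masked responses
#'
#' For each household x item domain x season, the latent question
#' assignment `z` is drawn from the randomizer; a sensitive assignment
#' yields `use ~ Bernoulli(pi_s(cell))` and, when used, a quantity category
#' from the ordered-logistic model (household covariates, generator
#' coefficients, taxon-group cutpoints); a nonsensitive assignment draws
#' from the unrelated item's prevalence and category distribution. The
#' marginal probability of an observed "yes" in a cell is therefore
#' `p_s * pi_s + (1 - p_s) * pi_ns`. The truth table retains `z` and the
#' latent use; the analysis table never contains either.
#'
#' @param households Data frame from [simulate_households()].
#' @param params A [true_params()].
#' @param design A validated [study_design()].
#' @param seed Integer seed; mandatory.
#' @return List with elements `truth` and `analysis` (data frames); the
#'   analysis table is the truth table minus the `z` and `latent_use`
#'   columns.
#' @export
simulate_responses <- function(households, params, design, seed) {
  if (missing(seed) || is.null(seed))
    stop("simulate_responses: 'seed' is required", call. = FALSE)
  validate_design(design)
  set.seed(seed)

  grid <- expand.grid(row = seq_len(nrow(households)),
                      item_domain = design$item_domains,
                      season = design$seasons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hh <- households[grid$row, , drop = FALSE]
  n <- nrow(grid)

  # per-row sensitive prevalence (errors if any stratum cell is missing)
  key <- paste(hh$municipality, hh$urbanization, grid$item_domain, grid$season)
  ps_tab <- params$pi_s
  tab_key <- paste(ps_tab$municipality, ps_tab$urbanization,
                   ps_tab$item_domain, ps_tab$season)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])[1L]
    stop("simulate_responses: no pi_s entry for cell: ", miss, call. = FALSE)
  }
  pi_s_row <- ps_tab$pi[idx]
  pi_ns_row <- params$pi_ns[design$nonsensitive_items[grid$item_domain]]

  p_s <- design$randomizer$p_s
  z <- stats::rbinom(n, 1L, p_s)                      # 1 = sensitive
  use <- integer(n)
  use[z == 1L] <- stats::rbinom(sum(z == 1L), 1L, pi_s_row[z == 1L])
  use[z == 0L] <- stats::rbinom(sum(z == 0L), 1L, pi_ns_row[z == 0L])

  # quantity categories for users
  K <- length(params$ns_quantity_probs)
  qcat <- integer(n)
  sens_user <- which(z == 1L & use == 1L)
  if (length(sens_user)) {
    x <- .generator_design_row(hh[sens_user, , drop = FALSE],
                               grid$season[sens_user])
    eta <- as.vector(x %*% params$quantity_betas[colnames(x)])
    taxon <- sub(":.*$", "", grid$item_domain[sens_user])
    qcat[sens_user] <- vapply(seq_along(sens_user), function(j) {
      kap <- params$quantity_cutpoints[[taxon[j]]]
      cum <- stats::plogis(kap - eta[j])        # P(cat <= k), k = 1..K-1
      1L + sum(stats::runif(1L) > cum)
    }, integer(1L))
  }
  ns_user <- which(z == 0L & use == 1L)
  if (length(ns_user)) {
    qcat[ns_user] <- sample.int(K, length(ns_user), replace = TRUE,
                                prob = params$ns_quantity_probs)
  }

  truth <- data.frame(
    hh[, c("household_id", "municipality", "urbanization", "residence_status",
           "management", "n_minors", "n_working_adults",
           "visits_urban", "visits_rural")],
    season = grid$season,
    item_domain = grid$item_domain,
    use = use,
    quantity_category = qcat,
    z = c("nonsensitive", "sensitive")[z + 1L],
    latent_use = ifelse(z == 1L, use, NA_integer_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  analysis <- truth[, setdiff(names(truth), c("z", "latent_use"))]
  list(truth = truth, analysis = analysis)
}

# Design-matrix row(s) for the generator's ordinal quantity model.
.generator_design_row <- function(hh, season) {
  cbind(
    municipality_manaus = as.integer(hh$municipality == "manaus"),
    urbanization_rural = as.integer(hh$urbanization == "rural"),
    urbanization_peri_urban = as.integer(hh$urbanization == "peri_urban"),
    residence_multisited = as.integer(hh$residence_status == "multisited"),
    season_dry = as.integer(season == "dry")
  )
}
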