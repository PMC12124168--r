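# True (generator) parameters: sensitive prevalences per cell, unrelated-item
# prevalences, ordinal quantity model, and covariate-generator coefficients.

#' True parameters for the synthetic-data generator
#'
#' Bundles everything the generator needs to produce a survey dataset with a
#' known ground truth: per-cell sensitive prevalences `pi_s` (one value per
#' municipality x urbanization x item domain x season), unrelated-item
#' prevalences `pi_ns`, the category distribution of the unrelated item's
#' quantity answer, the ordered-logistic quantity model (cutpoints and
#' covariate coefficients on the log-odds scale), and the covariate
#' generator settings (`glm_betas`).
#'
#' @param pi_s Data frame with columns `municipality`, `urbanization`,
#'   `item_domain`, `season`, `pi` (values in `[0,1]`).
#' @param pi_ns Named numeric vector: unrelated item -> prevalence in `[0,1]`.
#' @param ns_quantity_probs Probabilities of quantity categories `1..K` for
#'   the unrelated item, conditional on a "yes"; must sum to 1.
#' @param quantity_cutpoints Named list: taxon group -> strictly increasing
#'   cutpoint vector (length `K - 1` for `K` non-zero bins).
#' @param quantity_betas Named numeric vector of generator coefficients on
#'   the log-odds scale (names are design-matrix columns, see
#'   [quantity_design_matrix()]).
#' @param glm_betas List of covariate-generator settings (visit-count
#'   negative binomial means/IRRs/sizes, household-structure probabilities).
#' @return Object of class `true_params`.
#' @seealso [default_true_params()]
#' @export
true_params <- function(pi_s, pi_ns, ns_quantity_probs,
                        quantity_cutpoints, quantity_betas, glm_betas) {
  if (any(pi_s$pi < 0 | pi_s$pi > 1))
    stop("true_params: pi_s values must lie in [0,1]", call. = FALSE)
  if (any(pi_ns < 0 | pi_ns > 1))
    stop("true_params: pi_ns values must lie in [0,1]", call. = FALSE)
  if (abs(sum(ns_quantity_probs) - 1) > 1e-8)
    stop("true_params: ns_quantity_probs must sum to 1", call. = FALSE)
  for (nm in names(quantity_cutpoints)) {
    k <- quantity_cutpoints[[nm]]
    if (length(k) > 1L && any(diff(k) <= 0))
      stop("true_params: quantity_cutpoints must be strictly increasing (",
           nm, ")", call. = FALSE)
  }
  structure(
    list(pi_s = pi_s, pi_ns = pi_ns, ns_quantity_probs = ns_quantity_probs,
         quantity_cutpoints = quantity_cutpoints,
         quantity_betas = quantity_betas, glm_betas = glm_betas),
    class = "true_params"
  )
}

# Dry-season prevalence table (percent). Cells printed in the study are used
# verbatim; the remaining cells are filled once with values that respect the
# printed ordering (rural >= peri-urban >= urban; consumption higher in the
# small town). Wet season is 0.9 x dry: use was somewhat higher in the dry
# season but did not differ significantly.
.default_pi_s_dry <- function() {
  g <- function(domain, man_r, man_p, man_u, car_r, car_p, car_u) {
    data.frame(
      municipality = rep(c("manaus", "carauari"), each = 3L),
      urbanization = rep(c("rural", "peri_urban", "urban"), 2L),
      item_domain = domain,
      pi = c(man_r, man_p, man_u, car_r, car_p, car_u) / 100,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    g("mammals_birds:consumption", 50, 40, 22, 92, 80, 57),
    g("chelonians:consumption",    60, 45, 28, 90, 80, 61),
    g("mammals_birds:barter",      35, 30, 17, 55, 50, 30),
    g("chelonians:barter",         25, 13, 14, 70, 79, 20),
    g("mammals_birds:trade",       30, 28, 21, 46, 35,  7),
    g("chelonians:trade",          30, 44, 16, 45, 35, 21)
  )
}

#' Default generator parameters
#'
#' Sensitive prevalences are seeded from the study's printed dry-season
#' estimates (e.g. urban mammal/bird consumption 22% in Manaus, 57% in
#' Carauari; peri-urban chelonian barter 79% in Carauari) with unprinted
#' cells filled to respect the printed ordering; wet-season values are 0.9
#' times the dry values. Unrelated items are common legal goods, so their
#' prevalence defaults to 0.5. Quantity coefficients use the study's
#' consumption-model odds ratios (rural 7.56, peri-urban 3.42, multisited
#' 2.51, large city 0.14, dry season 1.55 -- log scale). Visit-count
#' generators are negative binomial with incidence rate ratios from the
#' visit models (Manaus 1.30 and peri-urban 3.02 for urban visits; Manaus
#' 0.24 and multisited 4.78 for rural visits) and dispersions chosen so the
#' marginal spread is of the order the study reports (roughly 22 urban
#' visits, 6.6 rural visits per season).
#'
#' @param design A [study_design()]; used for the unrelated-item labels.
#' @return A [true_params()] object.
#' @export
default_true_params <- function(design = study_design()) {
  dry <- .default_pi_s_dry()
  wet <- dry
  wet$pi <- round(0.9 * wet$pi, 4)
  dry$season <- "dry"
  wet$season <- "wet"
  pi_s <- rbind(dry, wet)

  pi_ns <- rep(0.5, length(design$nonsensitive_items))
  names(pi_ns) <- design$nonsensitive_items

  true_params(
    pi_s = pi_s,
    pi_ns = pi_ns,
    ns_quantity_probs = c(0.4, 0.3, 0.2, 0.1),
    quantity_cutpoints = list(chelonians = c(-1, 0.5, 2),
                              mammals_birds = c(-1, 0.5, 2)),
    quantity_betas = c(municipality_manaus = log(0.14),
                       urbanization_rural = log(7.56),
                       urbanization_peri_urban = log(3.42),
                       residence_multisited = log(2.51),
                       season_dry = log(1.55)),
    glm_betas = list(
      visits_urban = list(mu0 = 6, irr_manaus = 1.30, irr_peri_urban = 3.02,
                          size = 0.5),
      visits_rural = list(mu0 = 4, irr_manaus = 0.24, irr_multisited = 4.78,
                          size = 0.85),
      multisited_prob = c(rural = 0.25, peri_urban = 0.28, urban = 0.14),
      dual_adult = list(p0 = 0.60, or_manaus = 0.41, or_rural = 1.60,
                        or_peri_urban = 3.25),
      minors_lambda = 1.3,
      working_lambda = 1.0
    )
  )
}

#' Look up a cell's sensitive prevalence
#' @param params A [true_params()].
#' @param municipality,urbanization,domain,season Cell key.
#' @return Prevalence in `[0,1]`; error if the cell is absent.
#' @export
pi_s_lookup <- function(params, municipality, urbanization, domain, season) {
  p <- params$pi_s
  hit <- p$municipality == municipality & p$urbanization == urbanization &
    p$item_domain == domain & p$season == season
  if (sum(hit) != 1L)
    stop(sprintf("pi_s_lookup: cell (%s, %s, %s, %s) not in params",
                 municipality, urbanization, domain, season), call. = FALSE)
  p$pi[hit]
}
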