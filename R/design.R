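# Study design: strata, seasons, item domains, randomizer.

MUNICIPALITIES <- c("carauari", "manaus")   # small_town, large_city
URBANIZATIONS  <- c("rural", "peri_urban", "urban")
SEASONS        <- c("dry", "wet")
TAXON_GROUPS   <- c("chelonians", "mammals_birds")
USE_TYPES      <- c("consumption", "barter", "trade")

#' Item-domain label
#'
#' One item domain is a (taxon group, use type) pair, e.g. chelonian barter.
#' @param taxon_group `"chelonians"` or `"mammals_birds"`.
#' @param use_type `"consumption"`, `"barter"` or `"trade"`.
#' @return Character label `"<taxon_group>:<use_type>"`.
#' @export
item_domain <- function(taxon_group, use_type) {
  paste(taxon_group, use_type, sep = ":")
}

#' All item domains of the default design
#' @return Character vector of the 6 domain labels.
#' @export
all_item_domains <- function() {
  as.vector(outer(TAXON_GROUPS, USE_TYPES, item_domain))
}

#' Stratified two-municipality study design
#'
#' Describes the survey: strata (municipality x urbanization category with
#' per-stratum household counts), the two seasons every item is asked about,
#' the item domains (taxon group x use type), the unrelated-item labels, and
#' the domino randomizer. The default reproduces the field design: 782
#' households, 509 in Manaus (120 rural, 90 peri-urban, 299 urban) and 273
#' in Carauari (73 rural, 41 peri-urban, 159 urban).
#'
#' @param strata Data frame with columns `municipality`, `urbanization`,
#'   `n_households`.
#' @param seasons Ordered character vector of seasons.
#' @param item_domains Character vector of domain labels (see
#'   [item_domain()]).
#' @param nonsensitive_items Character vector naming the unrelated item used
#'   for each domain (recycled to the number of domains).
#' @param randomizer A [randomizer_design()].
#' @return Object of class `study_design`.
#' @export
study_design <- function(strata = default_strata(),
                         seasons = SEASONS,
                         item_domains = all_item_domains(),
                         nonsensitive_items = paste0("legal_item_",
                                                     seq_along(item_domains)),
                         randomizer = randomizer_design()) {
  nonsensitive_items <- rep_len(nonsensitive_items, length(item_domains))
  names(nonsensitive_items) <- item_domains
  structure(
    list(strata = strata, seasons = seasons, item_domains = item_domains,
         nonsensitive_items = nonsensitive_items, randomizer = randomizer),
    class = "study_design"
  )
}

#' @rdname study_design
#' @export
default_strata <- function() {
  data.frame(
    municipality = rep(c("manaus", "carauari"), each = 3L),
    urbanization = rep(c("rural", "peri_urban", "urban"), 2L),
    n_households = c(120L, 90L, 299L, 73L, 41L, 159L),
    stringsAsFactors = FALSE
  )
}

#' Validate a study design
#'
#' Checks every structural invariant: recognized stratum labels, positive
#' integer stratum sizes, no duplicate strata, at least one season and item
#' domain, one unrelated item per domain, and a coherent randomizer
#' (`p_s = n_sensitive / n_total`). Returns the design unchanged on success.
#'
#' @param design A [study_design()].
#' @return `design`, invisibly unchanged, if all invariants hold.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "study_design"))
    stop("validate_design: not a study_design object", call. = FALSE)
  st <- design$strata
  req <- c("municipality", "urbanization", "n_households")
  if (!is.data.frame(st) || !all(req %in% names(st)))
    stop("validate_design: strata must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(st) == 0L)
    stop("validate_design: strata: no strata defined", call. = FALSE)
  if (!all(st$municipality %in% MUNICIPALITIES))
    stop("validate_design: municipality: unknown label", call. = FALSE)
  if (!all(st$urbanization %in% URBANIZATIONS))
    stop("validate_design: urbanization: unknown label", call. = FALSE)
  if (anyDuplicated(st[, c("municipality", "urbanization")]))
    stop("validate_design: strata: duplicate stratum", call. = FALSE)
  if (any(is.na(st$n_households)) || any(st$n_households <= 0) ||
      any(st$n_households != as.integer(st$n_households)))
    stop("validate_design: n_households: sizes must be positive integers",
         call. = FALSE)
  if (length(design$seasons) < 1L)
    stop("validate_design: seasons: none defined", call. = FALSE)
  if (length(design$item_domains) < 1L)
    stop("validate_design: item_domains: none defined", call. = FALSE)
  if (!identical(sort(names(design$nonsensitive_items)),
                 sort(design$item_domains)))
    stop("validate_design: nonsensitive_items: must map every item domain",
         call. = FALSE)
  rd <- design$randomizer
  if (!inherits(rd, "randomizer_design"))
    stop("validate_design: randomizer: not a randomizer_design", call. = FALSE)
  if (rd$n_sensitive > rd$n_total || rd$n_sensitive < 0)
    stop("validate_design: randomizer: n_sensitive outside [0, n_total]",
         call. = FALSE)
  if (!isTRUE(all.equal(rd$p_s, rd$n_sensitive / rd$n_total)))
    stop("validate_design: randomizer: p_s must equal n_sensitive/n_total",
         call. = FALSE)
  invisible(design)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d strata, %d households total, %d item domains, %d seasons\n",
              nrow(x$strata), sum(x$strata$n_households),
              length(x$item_domains), length(x$seasons)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}
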