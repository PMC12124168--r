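# Survey file I/O. The analysis-facing file must never contain the latent
# question assignment, so the truth/analysis split is enforced at write and
# read time, not left to caller discipline.

ANALYSIS_COLUMNS <- c("household_id", "municipality", "urbanization",
                      "residence_status", "management", "n_minors",
                      "n_working_adults", "visits_urban", "visits_rural",
                      "season", "item_domain", "use", "quantity_category")
TRUTH_COLUMNS <- c(ANALYSIS_COLUMNS, "z", "latent_use")
HOUSEHOLD_COLUMNS <- c("household_id", "municipality", "urbanization",
                       "residence_status", "management", "n_minors",
                       "n_working_adults", "visits_urban", "visits_rural")

#' Write a survey response table
#'
#' Writes UTF-8 CSV with a mandatory header and empty fields for `NA`. A
#' truth table (containing the latent assignment `z`) must be written with
#' `truth = TRUE` and gets the `.truth.csv` suffix enforced; an analysis
#' table is refused if it contains any latent column.
#'
#' @param records Response data frame ([simulate_responses()] element).
#' @param path Output path.
#' @param truth Logical; is this the truth (latent-including) table?
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path, truth = FALSE) {
  want <- if (truth) TRUTH_COLUMNS else ANALYSIS_COLUMNS
  if (!truth && any(c("z", "latent_use") %in% names(records)))
    stop("write_survey_csv: latent columns present in analysis-facing table; ",
         "write with truth = TRUE to a .truth.csv file", call. = FALSE)
  if (!all(want %in% names(records)))
    stop("write_survey_csv: missing columns: ",
         paste(setdiff(want, names(records)), collapse = ", "), call. = FALSE)
  if (truth && !grepl("\\.truth\\.csv$", path))
    stop("write_survey_csv: truth tables must use the .truth.csv suffix",
         call. = FALSE)
  utils::write.csv(records[, want], path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a survey response table
#'
#' Parses the CSV written by [write_survey_csv()] and enforces the schema
#' invariants: known header, binary `use`, `quantity_category = 0` exactly
#' when `use = 0`, non-negative counts, and exclusive applicability of
#' `visits_urban` / `visits_rural`. Violations raise a parse error naming
#' the offending data line.
#'
#' @param path CSV path.
#' @param truth Logical; expect the truth schema (with `z`, `latent_use`)?
#' @return Validated data frame.
#' @export
read_survey_csv <- function(path, truth = FALSE) {
  want <- if (truth) TRUTH_COLUMNS else ANALYSIS_COLUMNS
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if (!identical(sort(names(df)), sort(want))) {
    extra <- setdiff(names(df), want)
    if (length(extra) && !truth && any(c("z", "latent_use") %in% extra))
      stop("read_survey_csv: latent column(s) ",
           paste(intersect(extra, c("z", "latent_use")), collapse = ", "),
           " found in analysis-facing file", call. = FALSE)
    stop("read_survey_csv: header mismatch; unexpected: ",
         paste(extra, collapse = ", "), "; missing: ",
         paste(setdiff(want, names(df)), collapse = ", "), call. = FALSE)
  }
  .fail_line <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      stop(sprintf("read_survey_csv: line %d: %s",
                   which(bad)[1L] + 1L, msg), call. = FALSE)
  }
  .fail_line(!is.na(df$visits_urban) & df$visits_urban < 0,
             "visits_urban is negative")
  .fail_line(!is.na(df$visits_rural) & df$visits_rural < 0,
             "visits_rural is negative")
  .fail_line(!is.na(df$visits_urban) & !is.na(df$visits_rural),
             "both visits_urban and visits_rural populated")
  .fail_line(is.na(df$visits_urban) & is.na(df$visits_rural),
             "neither visits column populated")
  .fail_line(!(df$use %in% c(0L, 1L)), "use is not binary")
  .fail_line((df$quantity_category == 0L) != (df$use == 0L),
             "quantity_category = 0 must hold exactly when use = 0")
  .fail_line(df$n_minors < 0 | df$n_working_adults < 0,
             "negative household count")
  df[, want]
}

#' Write / read a household table
#' @param households Data frame from [simulate_households()].
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_household_csv <- function(households, path) {
  if (!all(HOUSEHOLD_COLUMNS %in% names(households)))
    stop("write_household_csv: missing columns", call. = FALSE)
  utils::write.csv(households[, HOUSEHOLD_COLUMNS], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_household_csv
#' @export
read_household_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if (!identical(sort(names(df)), sort(HOUSEHOLD_COLUMNS)))
    stop("read_household_csv: header mismatch", call. = FALSE)
  df[, HOUSEHOLD_COLUMNS]
}

#' Write-then-read identity for survey records
#'
#' Serializes `records` to a temporary CSV and reads them back, asserting
#' that the roundtrip is semantically lossless (missing fields stay
#' missing, never zero).
#'
#' @param records Analysis-facing response records.
#' @return The re-read records.
#' @export
survey_io_roundtrip <- function(records) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_survey_csv(records, path)
  back <- read_survey_csv(path)
  if (!isTRUE(all.equal(as.data.frame(records[, ANALYSIS_COLUMNS]),
                        back, check.attributes = FALSE)))
    stop("survey_io_roundtrip: roundtrip altered the records", call. = FALSE)
  back
}

#' Read a generator configuration
#'
#' YAML mirroring the study design and true parameters, with a mandatory
#' top-level integer `seed`. Only the fields present are overridden;
#' everything else keeps the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `design`, `params`, `seed`.
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed))
    stop("read_generator_config: top-level 'seed' is required", call. = FALSE)
  design <- study_design()
  if (!is.null(cfg$design$strata)) {
    st <- do.call(rbind, lapply(cfg$design$strata, function(s)
      data.frame(municipality = s$municipality, urbanization = s$urbanization,
                 n_households = as.integer(s$n_households),
                 stringsAsFactors = FALSE)))
    design$strata <- st
  }
  if (!is.null(cfg$design$randomizer)) {
    rz <- cfg$design$randomizer
    design$randomizer <- randomizer_design(rz$n_total, rz$n_sensitive)
  }
  params <- default_true_params(design)
  if (!is.null(cfg$params$pi_ns))
    params$pi_ns[] <- as.numeric(cfg$params$pi_ns)
  if (!is.null(cfg$params$ns_quantity_probs))
    params$ns_quantity_probs <- as.numeric(cfg$params$ns_quantity_probs)
  validate_design(design)
  list(design = design, params = params, seed = as.integer(cfg$seed))
}
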