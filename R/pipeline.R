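# Config-driven pipeline: generate -> estimate -> report, fully seeded.
# Every stage seed is derived from the single master seed, all artifacts are
# declared in a JSON manifest of content hashes, and a rerun from the same
# config is hash-identical (timestamps live only in the log, which is not a
# manifest artifact).

#' Read and validate a pipeline configuration
#'
#' YAML with a mandatory integer `seed`; optional `workdir`, `generator`
#' (study-design / parameter overrides as in [read_generator_config()]),
#' `mcmc` settings, `models` (which prevalence domains, quantity models and
#' GLMs to run) and `report` options.
#'
#' @param path YAML config path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("read_pipeline_config: no such config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed))
    stop("read_pipeline_config: master 'seed' is mandatory", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$workdir)) cfg$workdir <- "rrtsurvey_out"
  m <- cfg$mcmc
  cfg$mcmc <- mcmc_config(
    n_burnin = if (is.null(m$n_burnin)) 50000L else m$n_burnin,
    n_samples = if (is.null(m$n_samples)) 25000L else m$n_samples,
    n_chains = if (is.null(m$n_chains)) 2L else m$n_chains,
    thin = if (is.null(m$thin)) 1L else m$thin,
    seed = cfg$seed
  )
  if (is.null(cfg$models)) cfg$models <- list()
  if (is.null(cfg$models$prevalence)) cfg$models$prevalence <- TRUE
  if (is.null(cfg$models$glms))
    cfg$models$glms <- c("visits_urban", "visits_rural",
                         "dual_adult", "dependency")
  structure(cfg, class = "pipeline_config")
}

.cfg_design_params <- function(cfg) {
  design <- study_design()
  gen <- cfg$generator
  if (!is.null(gen$design$strata)) {
    design$strata <- do.call(rbind, lapply(gen$design$strata, function(s)
      data.frame(municipality = s$municipality, urbanization = s$urbanization,
                 n_households = as.integer(s$n_households),
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(gen$design$randomizer))
    design$randomizer <- randomizer_design(gen$design$randomizer$n_total,
                                           gen$design$randomizer$n_sensitive)
  params <- default_true_params(design)
  if (!is.null(gen$params$pi_ns)) params$pi_ns[] <- as.numeric(gen$params$pi_ns)
  if (!is.null(gen$params$ns_quantity_probs))
    params$ns_quantity_probs <- as.numeric(gen$params$ns_quantity_probs)
  validate_design(design)
  list(design = design, params = params)
}

.log_line <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = logfile, append = TRUE)
  message(line)
}

#' Run the survey pipeline
#'
#' Executes the requested stages in order on a validated config:
#' `generate` simulates households and masked responses and writes the
#' household, truth, and analysis CSVs; `estimate` fits the per-cell
#' prevalence model, any configured quantity models, and the visit /
#' household-structure GLMs; `report` renders the prevalence table and a
#' plain-text report. A JSON manifest maps every declared artifact to its
#' MD5 content hash; a failure in any stage aborts with the stage and
#' model/cell identifier in the error.
#'
#' @param config Path to a YAML config or a `pipeline_config`.
#' @param stages Character subset of `c("generate", "estimate", "report")`
#'   (`"all"` for everything, the default).
#' @param seed Optional master-seed override.
#' @param workdir Optional working-directory override.
#' @return The manifest, invisibly: named list artifact -> MD5 hash (also
#'   written to `manifest.json`).
#' @export
run_pipeline <- function(config, stages = "all", seed = NULL, workdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$mcmc$seed <- as.integer(seed)
  }
  if (!is.null(workdir)) cfg$workdir <- workdir
  if (identical(stages, "all")) stages <- c("generate", "estimate", "report")
  bad <- setdiff(stages, c("generate", "estimate", "report"))
  if (length(bad))
    stop("run_pipeline: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$workdir, "pipeline.log")
  artifacts <- character()
  add_artifact <- function(path) artifacts <<- c(artifacts, path)
  pth <- function(name) file.path(cfg$workdir, name)

  dp <- .cfg_design_params(cfg)

  if ("generate" %in% stages) {
    .log_line(logfile, "generate",
              sprintf("seed %d (households %d, responses %d)", cfg$seed,
                      derive_seed(cfg$seed, "households"),
                      derive_seed(cfg$seed, "responses")))
    hh <- simulate_households(dp$design, dp$params,
                              derive_seed(cfg$seed, "households"))
    resp <- simulate_responses(hh, dp$params, dp$design,
                               derive_seed(cfg$seed, "responses"))
    write_household_csv(hh, pth("households.csv"))
    write_survey_csv(resp$truth, pth("responses.truth.csv"), truth = TRUE)
    write_survey_csv(resp$analysis, pth("responses.csv"))
    add_artifact(pth("households.csv"))
    add_artifact(pth("responses.truth.csv"))
    add_artifact(pth("responses.csv"))
    .log_line(logfile, "generate",
              sprintf("%d households, %d response rows", nrow(hh),
                      nrow(resp$analysis)))
  }

  if ("estimate" %in% stages) {
    responses <- tryCatch(read_survey_csv(pth("responses.csv")),
                          error = function(e)
                            stop("run_pipeline: stage estimate: ",
                                 conditionMessage(e), call. = FALSE))
    households <- read_household_csv(pth("households.csv"))
    prev_cfg <- cfg$models$prevalence
    if (!isFALSE(prev_cfg)) {
      sub <- if (isTRUE(prev_cfg)) responses
             else responses[responses$item_domain %in% unlist(prev_cfg), ]
      est_mcmc <- cfg$mcmc
      est_mcmc$seed <- derive_seed(cfg$seed, "estimate-prevalence")
      .log_line(logfile, "estimate",
                sprintf("prevalence: %d cells, seed %d",
                        length(unique(interaction(sub$municipality,
                                                  sub$urbanization,
                                                  sub$item_domain,
                                                  sub$season))),
                        est_mcmc$seed))
      pi_ns_by_domain <- dp$params$pi_ns[dp$design$nonsensitive_items]
      names(pi_ns_by_domain) <- names(dp$design$nonsensitive_items)
      cells <- tryCatch(
        fit_prevalence_cells(sub, p_s = dp$design$randomizer$p_s,
                             pi_ns = pi_ns_by_domain,
                             mcmc = est_mcmc),
        error = function(e) stop("run_pipeline: stage estimate (prevalence): ",
                                 conditionMessage(e), call. = FALSE))
      attr(cells, "draws") <- NULL
      utils::write.csv(as.data.frame(cells), pth("prevalence_cells.csv"),
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
      add_artifact(pth("prevalence_cells.csv"))
    }
    for (qm in cfg$models$quantity) {
      dom <- qm$item_domain
      sub <- responses[responses$item_domain == dom, ]
      if (nrow(sub) == 0L)
        stop("run_pipeline: stage estimate (quantity ", dom,
             "): no responses", call. = FALSE)
      dm <- quantity_design_matrix(sub)
      pi_ns_dom <- dp$params$pi_ns[[dp$design$nonsensitive_items[[dom]]]]
      ns_probs <- c(1 - pi_ns_dom, pi_ns_dom * dp$params$ns_quantity_probs)
      spec <- quantity_model_spec(dp$design$randomizer$p_s, ns_probs)
      qmc <- cfg$mcmc
      qmc$seed <- derive_seed(cfg$seed, paste0("estimate-quantity-", dom))
      .log_line(logfile, "estimate",
                sprintf("quantity %s: n = %d, seed %d", dom, nrow(sub),
                        qmc$seed))
      fit <- tryCatch(
        fit_quantity_model(sub$quantity_category, dm$matrix, spec, qmc),
        error = function(e) stop("run_pipeline: stage estimate (quantity ",
                                 dom, "): ", conditionMessage(e),
                                 call. = FALSE))
      tab <- odds_ratio_summary(fit, dm$scale_record)
      fn <- pth(paste0("quantity_", gsub(":", "_", dom), ".csv"))
      utils::write.csv(tab, fn, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
      add_artifact(fn)
    }
    for (gm in cfg$models$glms) {
      .log_line(logfile, "estimate", paste("glm", gm))
      res <- tryCatch(.fit_pipeline_glm(gm, households),
                      error = function(e)
                        stop("run_pipeline: stage estimate (glm ", gm, "): ",
                             conditionMessage(e), call. = FALSE))
      fn <- pth(paste0("glm_", gm, ".csv"))
      utils::write.csv(as.data.frame(res), fn, row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
      add_artifact(fn)
    }
  }

  if ("report" %in% stages) {
    cells <- utils::read.csv(pth("prevalence_cells.csv"),
                             stringsAsFactors = FALSE)
    tab <- render_prevalence_table(cells)
    utils::write.csv(tab, pth("prevalence_table.csv"), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    add_artifact(pth("prevalence_table.csv"))
    rpt <- pth("report.txt")
    con <- file(rpt, open = "wt", encoding = "UTF-8")
    writeLines(c(
      "Prevalence of wild-meat use by municipality, urbanization, item domain, season",
      "(dry season June–December; wet season the remainder; whole-percent",
      " posterior means with equal-tailed 95% credible intervals)", ""), con)
    writeLines(sprintf("%-9s %-10s %-26s %-4s %s", tab$municipality,
                       tab$urbanization, tab$item_domain, tab$season,
                       tab$rendered), con)
    close(con)
    add_artifact(rpt)
    .log_line(logfile, "report", sprintf("%d table rows", nrow(tab)))
  }

  hashes <- tools::md5sum(sort(unique(artifacts)))
  manifest <- as.list(unname(hashes))
  names(manifest) <- basename(names(hashes))
  jsonlite::write_json(manifest, file.path(cfg$workdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_line(logfile, "manifest",
            sprintf("%d artifact(s) hashed", length(manifest)))
  invisible(manifest)
}

# The four household GLMs, with the study's codings and subsets: visit
# models use the wet-season visit counts; visits_urban is defined for rural
# and peri-urban households, visits_rural for urban households.
.fit_pipeline_glm <- function(name, households) {
  h <- households
  manaus <- as.integer(h$municipality == "manaus")
  multi <- as.integer(h$residence_status == "multisited")
  rural <- as.integer(h$urbanization == "rural")
  peri <- as.integer(h$urbanization == "peri_urban")
  switch(
    name,
    visits_urban = {
      i <- h$urbanization %in% c("rural", "peri_urban")
      fit_negbin_visits(h$visits_urban[i],
                        cbind(municipality_manaus = manaus[i],
                              residence_multisited = multi[i],
                              urbanization_peri_urban = peri[i]))
    },
    visits_rural = {
      i <- h$urbanization == "urban"
      fit_negbin_visits(h$visits_rural[i],
                        cbind(municipality_manaus = manaus[i],
                              residence_multisited = multi[i]))
    },
    dual_adult = fit_logistic_structure(
      as.integer(h$management == "dual_adult"),
      cbind(municipality_manaus = manaus, residence_multisited = multi,
            urbanization_rural = rural, urbanization_peri_urban = peri)),
    dependency = {
      dep <- dependency_measures(h$n_minors, h$n_working_adults,
                                 h$n_working_adults)
      fit_logistic_structure(
        dep$exceeds_flag,
        cbind(municipality_manaus = manaus, residence_multisited = multi,
              urbanization_rural = rural, urbanization_peri_urban = peri))
    },
    stop("unknown GLM model: ", name, call. = FALSE)
  )
}

#' Render the prevalence table
#'
#' One row per municipality x urbanization x item domain x season cell of
#' the full layout, with percent-scale posterior mean and 95% interval
#' bounds and the whole-percent rendering used in text reports. Cells
#' requested by the layout but absent from the summaries are rendered
#' explicitly as `"absent"`, never dropped silently; duplicate cell keys
#' are an error.
#'
#' @param summaries Data frame from [fit_prevalence_cells()] (or its CSV).
#' @param layout Optional data frame of cell keys (`municipality`,
#'   `urbanization`, `item_domain`, `season`); defaults to the full
#'   factorial over the default design.
#' @return Data frame with percent-scale `pct_mean`, `pct_low`, `pct_high`
#'   and a `rendered` column.
#' @export
render_prevalence_table <- function(summaries, layout = NULL) {
  keys <- c("municipality", "urbanization", "item_domain", "season")
  if (anyDuplicated(summaries[, keys]))
    stop("render_prevalence_table: duplicate cell keys in summaries",
         call. = FALSE)
  if (is.null(layout)) {
    layout <- expand.grid(municipality = MUNICIPALITIES,
                          urbanization = URBANIZATIONS,
                          item_domain = all_item_domains(),
                          season = SEASONS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    layout <- layout[layout$item_domain %in% summaries$item_domain, ]
  }
  skey <- do.call(paste, c(summaries[keys], sep = "|"))
  lkey <- do.call(paste, c(layout[keys], sep = "|"))
  idx <- match(lkey, skey)
  out <- layout
  out$pct_mean <- 100 * summaries$mean[idx]
  out$pct_low <- 100 * summaries$cri_low[idx]
  out$pct_high <- 100 * summaries$cri_high[idx]
  out$n_households <- summaries$n_households[idx]
  out$rendered <- ifelse(
    is.na(idx), "absent",
    sprintf("%.0f%% [95%% CI %.0f–%.0f]", out$pct_mean, out$pct_low,
            out$pct_high))
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Verbs: `generate`, `estimate`, `report`, `all`; flags `--config PATH`
#' (required), `--seed INT` (master-seed override), `--workdir DIR`.
#'
#' @param args Character vector of CLI arguments (defaults to the process
#'   arguments).
#' @return Exit status 0, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c("generate", "estimate", "report", "all")
  if (length(args) == 0L || !args[1L] %in% verbs)
    stop("usage: <generate|estimate|report|all> --config PATH [--seed INT] [--workdir DIR]",
         call. = FALSE)
  verb <- args[1L]
  args <- args[-1L]
  opt <- list(config = NULL, seed = NULL, workdir = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stop("run_cli: bad argument: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$config))
    stop("run_cli: --config is required", call. = FALSE)
  run_pipeline(opt$config,
               stages = if (verb == "all") "all" else verb,
               seed = if (is.null(opt$seed)) NULL else as.integer(opt$seed),
               workdir = opt$workdir)
  invisible(0L)
}
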