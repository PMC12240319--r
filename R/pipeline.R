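#' Run configuration for the pipeline
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Either `input_dir` (a directory of FAERS-style files) or `synthetic`
#' (a [synthetic_config()]) must be supplied.
#'
#' @param input_dir directory with DEMO/DRUG/REAC/OUTC/THER files, or `NULL`.
#' @param synthetic a `synthetic_config`, or `NULL`.
#' @param smq_path SMQ term-list path (`NULL` = shipped fixture).
#' @param dict_path drug-dictionary CSV path (`NULL` = shipped fixture).
#' @param targets target generics (subset of the dictionary's generics).
#' @param ic_ci_method IC interval method (see [ic_estimate()]).
#' @param stratify run the age-stratified analysis.
#' @param out_dir output directory for result CSVs (`NULL` = don't write).
#' @param seed integer seed recorded in run metadata (and used for synthetic
#'   generation when `synthetic` carries no explicit seed change).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL, smq_path = NULL,
                       dict_path = NULL, targets = statin_generics,
                       ic_ci_method = "noren", stratify = TRUE,
                       out_dir = NULL, seed = 1L) {
  if (is.null(input_dir) && is.null(synthetic)) {
    stop("run_config: supply input_dir or synthetic")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  for (p in c(smq_path, dict_path)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 smq_path = smq_path, dict_path = dict_path,
                 targets = targets, ic_ci_method = ic_ci_method,
                 stratify = isTRUE(stratify), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a YAML or JSON run configuration file
#'
#' Top-level keys mirror the [run_config()] arguments; a `synthetic` mapping
#' is passed to [synthetic_config()].
#'
#' @param path YAML (or JSON) file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn <- do.call(synthetic_config, raw$synthetic)
  }
  run_config(
    input_dir = raw$input_dir, synthetic = syn, smq_path = raw$smq_path,
    dict_path = raw$dict_path,
    targets = raw$targets %||% statin_generics,
    ic_ci_method = raw$ic_ci_method %||% "noren",
    stratify = raw$stratify %||% TRUE,
    out_dir = raw$out_dir, seed = raw$seed %||% 1L
  )
}

#' Run the full signal-detection pipeline
#'
#' Stages run in fixed order: ingest -> deduplication -> drug mapping /
#' primary-suspect filter -> DILI classification and temporal exclusion ->
#' per-drug contingency tables and signals (plus age strata) -> descriptive,
#' onset, dose-trend and annual analyses -> result tables. Every stage's
#' input/output cardinality lands in the attrition report; with identical
#' configuration and seed, re-running reproduces byte-identical outputs.
#'
#' @param config a `run_config` (or path to a YAML/JSON config file).
#' @return list of class `pipeline_result`: `signals`,
#'   `signals_stratified`, `demographics`, `onset`, `onset_comparison`,
#'   `annual_counts`, `dose_trend`, `cohort`, `attrition`, and (when
#'   `out_dir` is set) `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dict <- load_drug_dictionary(config$dict_path)
  smq <- load_smq_terms(config$smq_path)

  if (!is.null(config$synthetic)) {
    pv_log("stage ingest: generating synthetic database (n = %d)",
           config$synthetic$n_cases)
    db <- generate_faers(config$synthetic, smq = smq, dict = dict)
    tdir <- tempfile("faers_synth_")
    write_faers_tables(db, tdir)
    on.exit(unlink(tdir, recursive = TRUE), add = TRUE)
    tables <- read_faers_dir(tdir)
  } else {
    pv_log("stage ingest: reading %s", config$input_dir)
    tables <- read_faers_dir(config$input_dir)
  }

  cohort <- assemble_cohort(tables, dict = dict, smq = smq)
  signals <- signal_table(cohort, drugs = config$targets,
                          ic_ci_method = config$ic_ci_method)
  strat <- if (config$stratify) {
    stratified_signals(cohort, drugs = config$targets,
                       ic_ci_method = config$ic_ci_method)
  } else {
    NULL
  }
  demo_tbl <- demographics_table(cohort)
  samples <- onset_samples(cohort)
  onset_tbl <- onset_summary(samples)
  onset_cmp <- compare_onset(samples)
  annual <- annual_counts(cohort)
  dose <- dose_trend(cohort)

  ing <- tables$ingest_reports
  attrition <- tibble::tibble(
    stage = c("ingest_demo_rows", "deduplicated_cases", "statin_ps_cases",
              "temporal_excluded", "retained_cases", "statin_dili_cases"),
    n = c(ing$DEMO$accepted, cohort$report$dedup$n_cases,
          cohort$report$n_statin_cases + cohort$report$n_excluded_temporal,
          cohort$report$n_excluded_temporal, cohort$report$n_retained,
          cohort$report$n_statin_dili)
  )

  result <- list(signals = signals, signals_stratified = strat,
                 demographics = demo_tbl, onset = onset_tbl,
                 onset_comparison = onset_cmp, annual_counts = annual,
                 dose_trend = dose, cohort = cohort, attrition = attrition)
  if (!is.null(config$out_dir)) {
    tables_out <- list(signals = signals, demographics = demo_tbl,
                       onset = onset_tbl, annual_counts = annual,
                       dose_trend = dose$table, attrition = attrition)
    if (!is.null(strat)) tables_out$signals_stratified <- strat
    cfg_rec <- config
    cfg_rec$synthetic <- unclass(cfg_rec$synthetic)
    result$manifest <- write_results(tables_out, config$out_dir,
                                     seed = config$seed,
                                     config = unclass(cfg_rec))
  }
  structure(result, class = "pipeline_result")
}

#' Published per-drug signal statistics
#'
#' The per-drug summary rows of the published statin-DILI signal table
#' (DILI case count `a`, non-DILI case count `b`, ROR with 95% CI, IC with
#' 95% credibility interval), shipped as a CSV fixture. These are inputs for
#' cross-consistency validation — the comparator cells were not published,
#' so [recover_background()] reconstructs the shared background odds from
#' these rows.
#'
#' @return tibble `drug`, `a`, `b`, `ror`, `ror_l`, `ror_u`, `ic`, `ic_l`,
#'   `ic_u`, `starred` (published signal flag).
#' @export
printed_signal_table <- function() {
  path <- system.file("extdata", "printed_signal_table.csv",
                      package = "statindili", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Cross-validate the pipeline's formulas against published statistics
#'
#' Recomputes, from the shipped published-value fixtures, the
#' cross-consistency checks: hold-out prediction of per-drug ROR/IC values
#' via the recovered background odds, the dual decision rule applied to the
#' published interval bounds, and exact two-decimal proportion checks.
#'
#' @param tol_rel relative tolerance for ROR checks (default 1%).
#' @param tol_ic absolute tolerance in bits for IC checks (default 0.02).
#' @return tibble `check`, `value`, `expected`, `tolerance`, `pass`.
#' @export
validate_printed <- function(tol_rel = 0.01, tol_ic = 0.02) {
  tab <- printed_signal_table()
  fit_drugs <- c("atorvastatin", "rosuvastatin", "simvastatin",
                 "pravastatin")
  bg <- recover_background(tab[tab$drug %in% fit_drugs, ])
  row <- function(d) tab[tab$drug == d, ]
  pred_ror <- function(d) (row(d)$a / row(d)$b) / bg$q
  pred_ror_ci <- function(d, side) {
    r <- pred_ror(d)
    half <- 1.96 * sqrt(1 / row(d)$a + 1 / row(d)$b + 1e-6 + 1e-6)
    if (side == "l") r * exp(-half) else r * exp(half)
  }
  pred_ic <- function(d) {
    log2((row(d)$a / (row(d)$a + row(d)$b)) / bg$p)
  }
  checks <- tibble::tribble(
    ~check, ~value, ~expected, ~tolerance,
    "fluvastatin_ror", pred_ror("fluvastatin"), 6.90, 6.90 * tol_rel,
    "fluvastatin_ror_l", pred_ror_ci("fluvastatin", "l"), 5.89,
    5.89 * tol_rel,
    "fluvastatin_ror_u", pred_ror_ci("fluvastatin", "u"), 8.10,
    8.10 * tol_rel,
    "cerivastatin_ror", pred_ror("cerivastatin"), 13.33, 13.33 * tol_rel,
    "pitavastatin_ror_u", pred_ror_ci("pitavastatin", "u"), 2.48,
    2.48 * tol_rel,
    "fluvastatin_ic", pred_ic("fluvastatin"), 2.65, tol_ic,
    "cerivastatin_ic", pred_ic("cerivastatin"), 3.46, tol_ic,
    "share_atorvastatin_pct", proportion(4160, 7779), 53.48, 0,
    "hospitalization_pct", proportion(3108, 7779), 39.95, 0,
    "death_pct", proportion(679, 7779), 8.73, 0,
    "simvastatin_death_pct", proportion(184, 1514), 12.15, 0,
    "elderly_pct", proportion(3534, 7779), 45.43, 0
  )
  cls <- classify_signal(tab$a, tab$ror_l, tab$ic, tab$ic_l)
  decision <- tibble::tibble(
    check = paste0("signal_", tab$drug),
    value = as.numeric(cls$signal),
    expected = as.numeric(tab$starred),
    tolerance = 0
  )
  out <- dplyr::bind_rows(checks, decision)
  out$pass <- abs(out$value - out$expected) <= out$tolerance
  out
}
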