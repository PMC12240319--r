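#' Load a DILI SMQ preferred-term list
#'
#' The drug-induced liver injury event is defined operationally as any report
#' carrying at least one MedDRA Preferred Term from the narrow scope of the
#' hepatic-disorders Standardised MedDRA Query (SMQ 20000007). MedDRA itself
#' is licensed, so the package ships a synthetic stand-in term list
#' (`smq_dili_narrow_synthetic.txt`); users holding a MedDRA licence should
#' point this loader at the authoritative narrow-scope list, which the
#' pipeline consumes unchanged. The file format is one PT per line with `#`
#' comments.
#'
#' @param path term-list path; default is the shipped synthetic stand-in.
#' @return object of class `smq_term_set`: list with `smq_code`, `scope`,
#'   `terms` (original strings) and `keys` (normalised match keys).
#' @export
load_smq_terms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "smq_dili_narrow_synthetic.txt",
                                package = "statindili", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  terms <- unique(lines[nzchar(lines)])
  if (length(terms) == 0) stop("SMQ term list is empty: ", path)
  structure(list(smq_code = "20000007", scope = "narrow", terms = terms,
                 keys = .pt_key(terms)),
            class = "smq_term_set")
}

# Case-insensitive whitespace-normalised PT match key.
.pt_key <- function(x) toupper(stringr::str_squish(as.character(x)))

#' Classify a report's reactions against the SMQ
#'
#' A report is a DILI case iff at least one of its PTs is in the SMQ term
#' set; however many terms match, the case contributes exactly one DILI
#' record (multiple matched PTs within the same SMQ collapse).
#'
#' @param pts character vector of the report's Preferred Terms.
#' @param smq an `smq_term_set` from [load_smq_terms()].
#' @return list: `is_dili` (logical scalar), `matched_pts` (character vector
#'   of the matching terms, possibly empty).
#' @export
classify_dili <- function(pts, smq) {
  stopifnot(inherits(smq, "smq_term_set"))
  if (length(smq$keys) == 0) stop("empty SMQ term set")
  hit <- unique(pts[.pt_key(pts) %in% smq$keys])
  list(is_dili = length(hit) > 0, matched_pts = hit)
}

#' Temporal plausibility rule for pre-existing events
#'
#' A case is excluded when therapy demonstrably started after the adverse
#' event: both dates present and the start date strictly later than the event
#' date at the coarsest common precision. Equal dates, incomparable
#' precisions that truncate equal, or any missing date keep the case — a
#' conservative reading that never excludes on incomplete information.
#'
#' @param event_dt,earliest_start_dt canonical partial dates (vectors,
#'   recycled).
#' @return logical vector: `TRUE` = keep, `FALSE` = exclude.
#' @examples
#' temporal_exclusion_keep("20230401", "20230501")  # start after event: drop
#' temporal_exclusion_keep("20230401", "20230401")  # same day: keep
#' temporal_exclusion_keep("20230315", "2023")      # year vs day: keep
#' @export
temporal_exclusion_keep <- function(event_dt, earliest_start_dt) {
  cmp <- pd_compare(earliest_start_dt, event_dt)
  !(!is.na(cmp) & cmp == 1L)
}

#' Assemble the analysis universe and the DILI cohort
#'
#' Runs the case-building stages on deduplicated tables: primary-suspect
#' statin mapping, SMQ classification, therapy-start linkage and the temporal
#' exclusion. The retained universe keeps every deduplicated case in the
#' loaded database (statin-exposed or not) because the disproportionality
#' comparator is "all other reports in the database"; the DILI / non-DILI
#' partition reported in the demographics tables applies to the statin-exposed
#' subset.
#'
#' Therapy start linkage: the earliest `START_DT` among THER rows whose
#' `dsg_drug_seq` matches a PS-statin `drug_seq`; when no linked row exists,
#' the earliest start date across all the case's THER rows is used; for
#' non-statin cases the case-level earliest start is used directly.
#'
#' @param tables list with `demo`, `drug`, `reac`, `outc`, `ther` tibbles
#'   (as from [read_faers_dir()] or [generate_faers()]).
#' @param dict a `drug_dictionary`.
#' @param smq an `smq_term_set`.
#' @return object of class `dili_cohort`: list with
#' * `cases`: one row per retained case — `caseid`, `primaryid`, `statins`
#'   (list-column of PS statin generics, possibly empty), `has_statin`,
#'   `is_dili`, `matched_pts` (list-column), `age_years`, `age_group`
#'   (`"<65"`, `">=65"`, `"unknown"`), `sex`, `reporter`, `region`,
#'   `outcomes` (list-column), `event_dt`, `start_dt`, `onset_days`,
#'   `receipt_year`;
#' * `exposures`: case x statin rows with `dose_per_day_mg`;
#' * `excluded`: cases removed by the temporal rule;
#' * `report`: attrition bookkeeping (input, dedup, mapping, exclusion
#'   counts).
#' @export
assemble_cohort <- function(tables, dict = load_drug_dictionary(),
                            smq = load_smq_terms()) {
  dd <- dedupe_cases(tables$demo)
  demo <- dd$demo
  kept <- demo$primaryid
  drug <- filter_to_primaryids(tables$drug, kept)
  reac <- filter_to_primaryids(tables$reac, kept)
  outc <- filter_to_primaryids(tables$outc, kept)
  ther <- filter_to_primaryids(tables$ther, kept)

  ps <- select_primary_suspect(drug, dict)
  exposures <- ps$exposures

  # SMQ classification, vectorized: one row per case with any-match flag and
  # the set of matched PTs.
  reac$pt_key <- .pt_key(reac$pt)
  reac$in_smq <- reac$pt_key %in% smq$keys
  dili_flags <- reac |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      is_dili = any(.data$in_smq),
      matched_pts = list(unique(.data$pt[.data$in_smq])),
      .groups = "drop"
    )

  # earliest therapy start: statin-linked when possible, else case-level.
  ther_min <- ther |>
    dplyr::filter(!is.na(.data$start_dt)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_any = .pd_min(.data$start_dt), .groups = "drop")
  linked <- exposures |>
    dplyr::select("primaryid", "drug_seq") |>
    dplyr::inner_join(ther, by = c("primaryid", "drug_seq" = "dsg_drug_seq")) |>
    dplyr::filter(!is.na(.data$start_dt)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_linked = .pd_min(.data$start_dt), .groups = "drop")

  statin_sets <- exposures |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(statins = list(sort(unique(.data$generic))),
                     .groups = "drop")
  outc_sets <- outc |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = list(sort(unique(.data$outcome))),
                     .groups = "drop")

  cases <- demo |>
    dplyr::left_join(statin_sets, by = "primaryid") |>
    dplyr::left_join(dili_flags, by = "primaryid") |>
    dplyr::left_join(outc_sets, by = "primaryid") |>
    dplyr::left_join(linked, by = "primaryid") |>
    dplyr::left_join(ther_min, by = "primaryid")
  empty_chr <- list(character(0))
  cases$statins[vapply(cases$statins, is.null, logical(1))] <- empty_chr
  cases$matched_pts[vapply(cases$matched_pts, is.null, logical(1))] <- empty_chr
  cases$outcomes[vapply(cases$outcomes, is.null, logical(1))] <- empty_chr
  cases$is_dili[is.na(cases$is_dili)] <- FALSE
  cases$has_statin <- lengths(cases$statins) > 0
  cases$start_dt <- ifelse(!is.na(cases$start_linked), cases$start_linked,
                           cases$start_any)
  cases$age_group <- dplyr::case_when(
    is.na(cases$age_years) ~ "unknown",
    cases$age_years >= 65 ~ ">=65",
    .default = "<65"
  )
  cases$onset_days <- onset_days(cases$event_dt, cases$start_dt)

  keep <- temporal_exclusion_keep(cases$event_dt, cases$start_dt)
  excluded <- cases[!keep, ]
  cases <- cases[keep, ]
  exposures <- filter_to_primaryids(exposures, cases$primaryid)

  cols <- c("caseid", "primaryid", "statins", "has_statin", "is_dili",
            "matched_pts", "age_years", "age_group", "sex", "reporter",
            "region", "outcomes", "event_dt", "start_dt", "onset_days",
            "receipt_year")
  statin_n <- sum(cases$has_statin)
  report <- list(
    dedup = dd$report,
    drug_mapping = ps$report,
    n_retained = nrow(cases),
    n_statin_cases = statin_n,
    n_statin_dili = sum(cases$has_statin & cases$is_dili),
    n_excluded_temporal = nrow(excluded),
    n_background = nrow(cases) - statin_n
  )
  pv_log("cohort: %d cases retained (%d statin, %d statin-DILI), %d excluded",
         report$n_retained, statin_n, report$n_statin_dili,
         report$n_excluded_temporal)
  structure(list(cases = cases[cols], exposures = exposures,
                 excluded = excluded[cols], report = report),
            class = "dili_cohort")
}

# earliest of a vector of partial dates; right-zero-padding to 8 digits
# sorts a coarser date before its refinements, which is the conservative
# (earliest-possible) reading for a minimum.
.pd_min <- function(pd) {
  pd <- pd[!is.na(pd)]
  if (length(pd) == 0) return(NA_character_)
  pad <- paste0(pd, strrep("0", 8L - nchar(pd)))
  pd[order(pad)][1]
}

#' @export
print.dili_cohort <- function(x, ...) {
  cat("<dili_cohort> ", x$report$n_retained, " cases (",
      x$report$n_statin_cases, " statin-exposed, ",
      x$report$n_statin_dili, " statin DILI); ",
      x$report$n_excluded_temporal, " temporally excluded\n", sep = "")
  invisible(x)
}
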