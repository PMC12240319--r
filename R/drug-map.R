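#' The eight target statin generics
#'
#' Generic names (with WHO ATC codes in the shipped dictionary) of the eight
#' HMG-CoA reductase inhibitors the pipeline screens: atorvastatin,
#' cerivastatin, fluvastatin, lovastatin, pitavastatin, pravastatin,
#' rosuvastatin, simvastatin.
#' @export
statin_generics <- c("atorvastatin", "cerivastatin", "fluvastatin",
                     "lovastatin", "pitavastatin", "pravastatin",
                     "rosuvastatin", "simvastatin")

# Salt / hydrate suffix tokens stripped from the end of a normalised name.
.salt_tokens <- c("CALCIUM", "SODIUM", "POTASSIUM", "MAGNESIUM",
                  "HEMICALCIUM", "MONOHYDRATE", "ANHYDROUS", "TRIHYDRATE",
                  "SESQUIHYDRATE")

# Uppercase, trim, collapse internal whitespace, strip trailing salt tokens.
.normalize_key <- function(x) {
  key <- stringr::str_squish(toupper(as.character(x)))
  repeat {
    stripped <- stringr::str_remove(
      key, paste0(" (", paste(.salt_tokens, collapse = "|"), ")$"))
    if (identical(stripped, key)) break
    key <- stripped
  }
  key
}

#' Load a drug-name standardisation dictionary
#'
#' The dictionary replaces free-text drug-name NLP with a curated,
#' user-extensible lookup: a CSV with columns `raw_name`, `generic`,
#' `atc_code` mapping brands, salts and spellings to the eight statin
#' generics. Keys are normalised (uppercased, whitespace-collapsed, trailing
#' salt tokens stripped) and must be unique; every `generic` must be one of
#' [statin_generics].
#'
#' @param path CSV path; default is the dictionary shipped with the package.
#' @return an object of class `drug_dictionary`: list with `entries` (named
#'   character vector key -> generic) and `atc` (generic -> ATC code).
#' @export
load_drug_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "statin_dictionary.csv",
                                package = "statindili", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("raw_name", "generic", "atc_code") %in% names(tbl)))
  bad <- setdiff(unique(tbl$generic), statin_generics)
  if (length(bad)) stop("dictionary maps to unknown generic(s): ",
                        paste(bad, collapse = ", "))
  key <- .normalize_key(tbl$raw_name)
  if (anyDuplicated(key)) {
    stop("dictionary keys not unique after normalization: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  atc <- tbl[match(statin_generics, tbl$generic), "atc_code"]
  structure(list(entries = setNames(tbl$generic, key),
                 atc = setNames(atc, statin_generics)),
            class = "drug_dictionary")
}

#' Standardise raw drug names to statin generics
#'
#' Deterministic exact lookup of the normalised name; no substring or fuzzy
#' matching is attempted, so `"LIPITOR TABLET"` stays unmapped unless the
#' dictionary lists it. Unmapped names return `NA`.
#'
#' @param raw_name character vector of raw drug-name strings.
#' @param dict a `drug_dictionary` from [load_drug_dictionary()].
#' @return character vector of generic names, `NA` where unmapped.
#' @examples
#' dict <- load_drug_dictionary()
#' normalize_drug_name(c("LIPITOR", "Atorvastatin Calcium", "ASPIRIN"), dict)
#' @export
normalize_drug_name <- function(raw_name, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  unname(dict$entries[.normalize_key(raw_name)])
}

#' Select primary-suspect statin exposures
#'
#' Restricts DRUG entries to role `PS` (primary suspected) and to names the
#' dictionary maps to a statin generic. A report can carry more than one PS
#' statin; all are kept (one exposure row per distinct report x generic,
#' keeping the lowest `drug_seq` for therapy-date linkage). Daily dose in mg
#' is derived when the unit is mg and the frequency is a recognised schedule
#' (QD/BID/TID/QID/QOD/QW).
#'
#' @param drug_entries tibble of DRUG records (see [read_faers_table()]).
#' @param dict a `drug_dictionary`.
#' @return list with `exposures` (tibble: `primaryid`, `generic`, `drug_seq`,
#'   `dose_per_day_mg`) and `report` (counts of PS rows seen, mapped and
#'   unmapped).
#' @export
select_primary_suspect <- function(drug_entries, dict) {
  ps <- drug_entries[drug_entries$role == "PS", ]
  generic <- normalize_drug_name(ps$raw_name, dict)
  mapped <- !is.na(generic)
  exp <- tibble::tibble(
    primaryid = ps$primaryid[mapped],
    generic = generic[mapped],
    drug_seq = ps$drug_seq[mapped],
    dose_per_day_mg = daily_dose_mg(ps$dose_amount[mapped],
                                    ps$dose_unit[mapped],
                                    ps$dose_frequency[mapped])
  )
  exp <- exp |>
    dplyr::group_by(.data$primaryid, .data$generic) |>
    dplyr::summarise(
      drug_seq = min(.data$drug_seq),
      dose_per_day_mg = if (all(is.na(.data$dose_per_day_mg))) NA_real_ else
        min(.data$dose_per_day_mg, na.rm = TRUE),
      .groups = "drop"
    )
  list(
    exposures = exp,
    report = list(
      n_ps_rows = nrow(ps),
      n_mapped = sum(mapped),
      n_unmapped = sum(!mapped),
      unmapped_names = head(sort(unique(ps$raw_name[!mapped])), 50)
    )
  )
}

# Daily dose in mg; NA unless unit is mg and frequency is recognised
# (missing frequency treated as once daily).
daily_dose_mg <- function(amount, unit, freq) {
  n <- length(amount)
  unit <- toupper(trimws(rep_len(as.character(unit), n)))
  freq <- toupper(trimws(rep_len(as.character(freq), n)))
  mult <- c(QD = 1, QOD = 0.5, BID = 2, TID = 3, QID = 4, QW = 1 / 7)
  fm <- unname(mult[freq])
  fm[is.na(freq) | freq == ""] <- 1
  out <- as.numeric(amount) * fm
  out[!(unit %in% c("MG", "MILLIGRAM"))] <- NA_real_
  out
}
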