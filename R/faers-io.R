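#' @title FAERS quarterly table ingestion
#' @name faers_io
#' @description
#' FAERS quarterly extracts are "$"-delimited ASCII files with a header line.
#' There is no quoting in the dialect, so a record is simply one line split on
#' `$`; lines whose field count disagrees with the header are rejected (and
#' counted), never fatal. Column binding is header-driven and case-insensitive
#' because field order and naming drifted across quarters (e.g. `SEX` vs the
#' older `GNDR_COD`). Unknown extra columns are ignored.
NULL

# Per-table required / recognised columns. Names on the right are the raw
# FAERS headers accepted (first present wins).
.faers_schema <- list(
  DEMO = list(
    required = c(primaryid = "PRIMARYID", caseid = "CASEID", fda_dt = "FDA_DT"),
    optional = list(
      event_dt = "EVENT_DT", age = "AGE", age_cod = "AGE_COD",
      sex = c("SEX", "GNDR_COD"), occp_cod = "OCCP_COD",
      country = c("OCCR_COUNTRY", "REPORTER_COUNTRY")
    )
  ),
  DRUG = list(
    required = c(primaryid = "PRIMARYID", drug_seq = "DRUG_SEQ",
                 role = "ROLE_COD", raw_name = "DRUGNAME"),
    optional = list(dose_amount = "DOSE_AMT", dose_unit = "DOSE_UNIT",
                    dose_frequency = "DOSE_FREQ")
  ),
  REAC = list(
    required = c(primaryid = "PRIMARYID", pt = "PT"),
    optional = list()
  ),
  OUTC = list(
    required = c(primaryid = "PRIMARYID", outcome = "OUTC_COD"),
    optional = list()
  ),
  THER = list(
    required = c(primaryid = "PRIMARYID", dsg_drug_seq = "DSG_DRUG_SEQ"),
    optional = list(start_dt = "START_DT")
  )
)

.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.role_codes <- c("PS", "SS", "C", "I")

#' Convert a reported age to years
#'
#' FAERS ages carry a unit code: `DEC` decades, `YR` years, `MON` months,
#' `WK` weeks, `DY` days, `HR` hours. Converted ages outside the plausibility
#' window 0-120 years (a guard against unit typos in real extracts) and
#' unrecognised units are coerced to `NA`.
#'
#' @param age_value numeric vector of reported ages (nonnegative).
#' @param age_unit character vector of unit codes (recycled).
#' @return numeric vector of ages in years, `NA` where not derivable.
#' @examples
#' age_in_years(c(7, 780, 2000), c("DEC", "MON", "YR"))
#' @export
age_in_years <- function(age_value, age_unit) {
  n <- max(length(age_value), length(age_unit))
  v <- suppressWarnings(as.numeric(rep_len(age_value, n)))
  u <- toupper(trimws(rep_len(as.character(age_unit), n)))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
            DY = 1 / 365.25, HR = 1 / 8766)
  out <- v * unname(mult[u])
  out[is.na(out) | out < 0 | out > 120] <- NA_real_
  out
}

#' Map an ISO country code to a reporter region
#'
#' Regions follow the standard pharmacovigilance rollup: North America,
#' Europe, Asia, Oceania, South America, Africa, with anything absent or
#' unrecognised as "unspecified". The mapping ships as a versioned CSV asset
#' (`country_regions.csv`) so the rollup is reproducible and auditable.
#'
#' @param country character vector of ISO-3166 alpha-2 codes (or `NA`/empty).
#' @return character vector of region labels.
#' @examples
#' to_region(c("FR", "JP", "", "US"))
#' @export
to_region <- function(country) {
  map <- .region_map()
  key <- toupper(trimws(as.character(country)))
  out <- unname(map[key])
  out[is.na(out)] <- "unspecified"
  out
}

.region_env <- new.env(parent = emptyenv())

.region_map <- function() {
  if (is.null(.region_env$map)) {
    path <- system.file("extdata", "country_regions.csv",
                        package = "statindili", mustWork = TRUE)
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
    .region_env$map <- setNames(tbl$region, tbl$country)
  }
  .region_env$map
}

#' Read one FAERS-style quarterly table
#'
#' @param source path to a "$"-delimited text file, or a character vector of
#'   lines (header first).
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`.
#' @return a list with `records` (typed tibble, see Details) and `report`
#'   (row counts and per-reason rejection tallies).
#' @details Emitted columns per kind:
#' * DEMO: `primaryid`, `caseid`, `fda_dt`, `event_dt` (canonical partial
#'   dates), `age_value`, `age_unit`, `age_years`, `sex`
#'   (`female`/`male`/`unknown`), `reporter`, `country`, `region`,
#'   `receipt_year`.
#' * DRUG: `primaryid`, `drug_seq`, `role`, `raw_name`, `dose_amount`,
#'   `dose_unit`, `dose_frequency`.
#' * REAC: `primaryid`, `pt` (whitespace-normalised).
#' * OUTC: `primaryid`, `outcome` (one of the seven FDA codes).
#' * THER: `primaryid`, `dsg_drug_seq`, `start_dt`.
#'
#' A missing mandatory column is a hard error naming the column. Undecodable
#' or invariant-violating rows are rejected with a reason, not fatal.
#' @export
read_faers_table <- function(source, table_kind = c("DEMO", "DRUG", "REAC",
                                                    "OUTC", "THER")) {
  table_kind <- match.arg(table_kind)
  schema <- .faers_schema[[table_kind]]
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  if (length(lines) == 0) stop("empty source for ", table_kind, " table")
  header <- toupper(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]

  # bind each logical field to a physical column index
  bind <- function(cands) {
    hit <- match(cands, header)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[[1]] else NA_integer_
  }
  req_idx <- vapply(schema$required, bind, integer(1))
  if (anyNA(req_idx)) {
    miss <- schema$required[is.na(req_idx)]
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 table_kind, paste(miss, collapse = ", ")))
  }
  opt_idx <- vapply(schema$optional, bind, integer(1))

  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty fields are dropped by strsplit; tolerate short rows whose
  # missing trailing fields are all optional
  min_needed <- max(req_idx)
  bad_shape <- nf < min_needed | nf > length(header)
  reasons <- character(0)
  if (any(bad_shape)) {
    reasons <- c(reasons, setNames(sum(bad_shape), "field_count_mismatch"))
  }
  parts <- parts[!bad_shape]
  grab <- function(idx) {
    if (is.na(idx)) return(rep(NA_character_, length(parts)))
    out <- vapply(parts, function(p) if (idx <= length(p)) p[[idx]] else "",
                  character(1))
    out <- trimws(out)
    out[out == ""] <- NA_character_
    out
  }
  raw <- c(lapply(req_idx, grab), lapply(opt_idx, grab))
  tbl <- tibble::as_tibble(raw)

  keep <- rep(TRUE, nrow(tbl))
  drop_rows <- function(bad, why) {
    bad <- bad & keep
    if (any(bad)) reasons <<- c(reasons, setNames(sum(bad), why))
    keep <<- keep & !bad
  }
  drop_rows(is.na(tbl$primaryid), "missing_primaryid")

  if (table_kind == "DEMO") {
    drop_rows(is.na(tbl$caseid), "missing_caseid")
    tbl$fda_dt <- parse_partial_date(tbl$fda_dt)
    drop_rows(is.na(tbl$fda_dt), "unparseable_fda_dt")
    tbl$event_dt <- parse_partial_date(tbl$event_dt)
    tbl$age_value <- suppressWarnings(as.numeric(tbl$age))
    tbl$age_unit <- toupper(tbl$age_cod)
    tbl$age_years <- age_in_years(tbl$age_value, tbl$age_unit)
    sex <- toupper(tbl$sex %||% NA_character_)
    tbl$sex <- dplyr::case_match(sex, "F" ~ "female", "M" ~ "male",
                                 .default = "unknown")
    occ <- toupper(tbl$occp_cod %||% NA_character_)
    tbl$reporter <- dplyr::case_when(
      occ %in% c("MD", "PH", "OT", "HP", "RN") ~ "health_professional",
      occ %in% c("CN", "LW") ~ "non_health_professional",
      .default = "unknown"
    )
    tbl$country <- toupper(tbl$country)
    tbl$country[!grepl("^[A-Z]{2}$", tbl$country %||% "")] <- NA_character_
    tbl$region <- to_region(tbl$country)
    tbl$receipt_year <- pd_year(tbl$fda_dt)
    tbl <- tbl[c("primaryid", "caseid", "fda_dt", "event_dt", "age_value",
                 "age_unit", "age_years", "sex", "reporter", "country",
                 "region", "receipt_year")]
  } else if (table_kind == "DRUG") {
    tbl$drug_seq <- suppressWarnings(as.integer(tbl$drug_seq))
    drop_rows(is.na(tbl$drug_seq) | tbl$drug_seq < 1, "invalid_drug_seq")
    tbl$role <- toupper(tbl$role)
    drop_rows(!(tbl$role %in% .role_codes), "invalid_role_code")
    drop_rows(is.na(tbl$raw_name), "missing_drugname")
    tbl$dose_amount <- suppressWarnings(as.numeric(tbl$dose_amount))
    tbl <- tbl[c("primaryid", "drug_seq", "role", "raw_name",
                 "dose_amount", "dose_unit", "dose_frequency")]
  } else if (table_kind == "REAC") {
    tbl$pt <- stringr::str_squish(tbl$pt)
    tbl$pt[tbl$pt == ""] <- NA_character_
    drop_rows(is.na(tbl$pt), "empty_pt")
    tbl <- tbl[c("primaryid", "pt")]
  } else if (table_kind == "OUTC") {
    tbl$outcome <- toupper(tbl$outcome)
    drop_rows(!(tbl$outcome %in% .outcome_codes), "invalid_outcome_code")
    tbl <- tbl[c("primaryid", "outcome")]
  } else if (table_kind == "THER") {
    tbl$dsg_drug_seq <- suppressWarnings(as.integer(tbl$dsg_drug_seq))
    drop_rows(is.na(tbl$dsg_drug_seq) | tbl$dsg_drug_seq < 1,
              "invalid_dsg_drug_seq")
    tbl$start_dt <- parse_partial_date(tbl$start_dt)
    tbl <- tbl[c("primaryid", "dsg_drug_seq", "start_dt")]
  }

  records <- tbl[keep, ]
  n_physical <- length(body)
  report <- list(
    table_kind = table_kind,
    physical_rows = n_physical,
    accepted = nrow(records),
    rejected = n_physical - nrow(records),
    reject_reasons = reasons
  )
  if (report$rejected > 0) {
    pv_log("%s: accepted %d of %d rows (%d rejected)", table_kind,
           report$accepted, n_physical, report$rejected)
  }
  list(records = records, report = report)
}

#' Read a directory of FAERS-style tables
#'
#' Locates one file per table kind by prefix match (`DEMO*`, `DRUG*`, ...;
#' case-insensitive) and ingests each with [read_faers_table()].
#'
#' @param dir directory containing the five table files.
#' @return list with elements `demo`, `drug`, `reac`, `outc`, `ther` (typed
#'   tibbles) and `ingest_reports`.
#' @export
read_faers_dir <- function(dir) {
  kinds <- names(.faers_schema)
  files <- list.files(dir, full.names = TRUE)
  out <- list()
  reports <- list()
  for (k in kinds) {
    hit <- files[grepl(paste0("^", k), basename(files), ignore.case = TRUE)]
    if (length(hit) == 0) stop("no ", k, " file found in ", dir)
    res <- read_faers_table(hit[[1]], k)
    out[[tolower(k)]] <- res$records
    reports[[k]] <- res$report
  }
  out$ingest_reports <- reports
  out
}

#' Write result tables and run metadata
#'
#' Writes one CSV per named table (fixed column order as supplied; an empty
#' table yields a header-only CSV) plus `run_metadata.json` carrying the seed,
#' a configuration hash and per-table row counts. Output is deterministic:
#' identical inputs reproduce byte-identical files.
#'
#' @param tables named list of data frames.
#' @param destination output directory (created if needed).
#' @param seed integer seed recorded in the metadata (or `NA`).
#' @param config optional list recorded (hashed) in the metadata.
#' @return tibble manifest: `name`, `path`, `rows`, `md5`.
#' @export
write_results <- function(tables, destination, seed = NA_integer_,
                          config = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(destination)) stop("cannot create directory: ", destination)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(destination, paste0(nm, ".csv"))
    df <- tables[[nm]]
    # flatten list-columns for serialization
    is_list <- vapply(df, is.list, logical(1))
    for (col in names(df)[is_list]) {
      df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ";"),
                          character(1))
    }
    readr::write_csv(df, p, progress = FALSE)
    paths[nm] <- p
  }
  meta <- list(
    seed = seed,
    config_hash = config_hash(config),
    tables = lapply(tables, nrow)
  )
  meta_path <- file.path(destination, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  tibble::tibble(
    name = names(paths),
    path = unname(paths),
    rows = vapply(tables, nrow, integer(1)),
    md5 = unname(tools::md5sum(unname(paths)))
  )
}

# Internal: stable md5 hash of a configuration list.
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
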