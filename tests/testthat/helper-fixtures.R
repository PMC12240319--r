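# In-code fixture builders: tiny FAERS-style tables routed through the real
# ingest path so typed records are produced exactly as in production.

options(statindili.quiet = TRUE)

demo_header <- "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country"

parse_demo <- function(...) {
  read_faers_table(c(demo_header, ...), "DEMO")$records
}

parse_drug <- function(...) {
  read_faers_table(
    c("primaryid$drug_seq$role_cod$drugname$dose_amt$dose_unit$dose_freq",
      ...), "DRUG")$records
}

parse_reac <- function(...) {
  read_faers_table(c("primaryid$pt", ...), "REAC")$records
}

parse_outc <- function(...) {
  read_faers_table(c("primaryid$outc_cod", ...), "OUTC")$records
}

parse_ther <- function(...) {
  read_faers_table(c("primaryid$dsg_drug_seq$start_dt", ...), "THER")$records
}

# a minimal five-table bundle; rows given as "$"-joined strings
mk_tables <- function(demo, drug, reac, outc = character(0),
                      ther = character(0)) {
  list(demo = parse_demo(demo), drug = parse_drug(drug),
       reac = parse_reac(reac), outc = parse_outc(outc),
       ther = parse_ther(ther))
}

# bare universe for contingency tests: vectors of drug labels (NA =
# unexposed background case) and DILI flags
mk_universe <- function(drug, dili) {
  pid <- sprintf("p%03d", seq_along(drug))
  exposed <- !is.na(drug)
  list(
    cases = tibble::tibble(primaryid = pid, is_dili = dili,
                           has_statin = exposed),
    exposures = tibble::tibble(primaryid = pid[exposed],
                               generic = drug[exposed])
  )
}

# serialize a raw generated table to "$"-joined lines (header first)
faers_lines <- function(tbl) {
  m <- as.matrix(tbl)
  m[is.na(m)] <- ""
  body <- if (nrow(m)) apply(m, 1, paste, collapse = "$") else character(0)
  c(paste(colnames(m), collapse = "$"), body)
}

test_dict <- load_drug_dictionary()
test_smq <- load_smq_terms()
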