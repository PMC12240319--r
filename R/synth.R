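#' Configuration for the synthetic FAERS-like database generator
#'
#' Builds a validated generator configuration. The defaults are the study
#' conditions of the statin-DILI analysis this package implements: statin
#' shares proportional to the published per-drug report totals, planted
#' reporting odds ratios equal to the published per-drug values, a
#' comparator (background) DILI proportion of 0.01695 (odds 0.017244, the
#' value the published per-drug tables jointly imply), outcome mixes from the
#' published outcome distribution, and log-normal onset latencies centred on
#' the published per-drug median onset days.
#'
#' @param seed integer RNG seed; the generator is fully reproducible given
#'   the seed.
#' @param n_cases number of logical cases (before duplicate report
#'   versions).
#' @param drug_shares named probabilities over the eight statins plus a
#'   `background` bucket (must sum to 1). The default puts 20% of the
#'   database on statins.
#' @param background_dili_prob probability `p0` that a background-drug case
#'   is DILI; per-drug DILI odds are `ROR * p0 / (1 - p0)`.
#' @param drug_ror named planted RORs for the statins (background is 1).
#' @param stratum_ror optional data frame `drug`, `age_group`
#'   (`"<65"`/`">=65"`), `ror` overriding `drug_ror` within a stratum.
#' @param age_mix,sex_mix,reporter_mix,region_mix categorical distributions
#'   (each must sum to 1; see defaults for the category names).
#' @param outcome_probs list with numeric vectors `dili` and `non_dili` over
#'   the seven outcome codes plus `none` (each sums to 1).
#' @param onset_lognormal list with named `mu` (log-days, must cover every
#'   drug and `background`) and scalar `sigma`.
#' @param duplicate_rate probability a case emits a superseded extra report
#'   version.
#' @param hostile_ties if `TRUE`, duplicate versions share the survivor's
#'   receipt date so only the higher-PRIMARYID tie-break identifies the
#'   survivor.
#' @param brand_variant_rate probability a statin is written as a brand or
#'   salt form rather than the generic name.
#' @param concomitant_rate probability of an extra non-suspect drug row.
#' @param extra_pt_rate probability of a second reaction PT (for DILI cases a
#'   second matching term, exercising the one-record-per-SMQ collapse).
#' @param missing_date_rate probability that the event or start date is
#'   degraded (half absent, a quarter to month, a quarter to year
#'   precision).
#' @param year_range inclusive receipt-year range.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_cases = 50000L,
    drug_shares = NULL,
    background_dili_prob = 0.0169514,
    drug_ror = c(atorvastatin = 3.09, cerivastatin = 13.33,
                 fluvastatin = 6.90, lovastatin = 2.77,
                 pitavastatin = 1.88, pravastatin = 2.07,
                 rosuvastatin = 2.27, simvastatin = 2.96),
    stratum_ror = NULL,
    age_mix = c("<65" = 0.32, ">=65" = 0.36, unknown = 0.32),
    sex_mix = c(female = 0.475, male = 0.42, unknown = 0.105),
    reporter_mix = c(health_professional = 0.46,
                     non_health_professional = 0.43, unknown = 0.11),
    region_mix = c(north_america = 0.5727, europe = 0.2678, asia = 0.0412,
                   oceania = 0.0117, south_america = 0.0371,
                   africa = 0.0039, unspecified = 0.0656),
    outcome_probs = list(
      dili = c(DE = 0.0873, LT = 0.0755, HO = 0.3995, DS = 0.0185,
               CA = 0.0003, RI = 0.0058, OT = 0.3666, none = 0.0465),
      non_dili = c(DE = 0.0453, LT = 0.0349, HO = 0.1782, DS = 0.0537,
                   CA = 0.0013, RI = 0.0081, OT = 0.4033, none = 0.2752)
    ),
    onset_lognormal = list(
      mu = log(c(atorvastatin = 24.5, cerivastatin = 30, fluvastatin = 20,
                 lovastatin = 89, pitavastatin = 48, pravastatin = 41,
                 rosuvastatin = 21, simvastatin = 35, background = 30)),
      sigma = 1.5
    ),
    duplicate_rate = 0.1,
    hostile_ties = FALSE,
    brand_variant_rate = 0.3,
    concomitant_rate = 0.25,
    extra_pt_rate = 0.2,
    missing_date_rate = 0.45,
    year_range = c(2004L, 2023L)) {
  if (is.null(drug_shares)) {
    # per-drug all-report totals, statins as 20% of the loaded database
    totals <- c(atorvastatin = 82722, rosuvastatin = 42091,
                simvastatin = 31184, pravastatin = 6362,
                fluvastatin = 1584, lovastatin = 1487,
                pitavastatin = 1650, cerivastatin = 32)
    drug_shares <- c(0.2 * totals / sum(totals), background = 0.8)
  }
  cfg <- list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    drug_shares = drug_shares, background_dili_prob = background_dili_prob,
    drug_ror = drug_ror, stratum_ror = stratum_ror, age_mix = age_mix,
    sex_mix = sex_mix, reporter_mix = reporter_mix,
    region_mix = region_mix / sum(region_mix),
    outcome_probs = outcome_probs, onset_lognormal = onset_lognormal,
    duplicate_rate = duplicate_rate, hostile_ties = isTRUE(hostile_ties),
    brand_variant_rate = brand_variant_rate,
    concomitant_rate = concomitant_rate, extra_pt_rate = extra_pt_rate,
    missing_date_rate = missing_date_rate,
    year_range = as.integer(year_range)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

# Hard validation before any generation.
validate_synthetic_config <- function(cfg) {
  sums_to_1 <- function(x) abs(sum(x) - 1) < 1e-9
  stopifnot(cfg$n_cases > 0, length(cfg$seed) == 1)
  if (!sums_to_1(cfg$drug_shares)) stop("drug_shares must sum to 1")
  if (!("background" %in% names(cfg$drug_shares))) {
    stop("drug_shares must include a 'background' bucket")
  }
  probs <- c(cfg$drug_shares, cfg$age_mix, cfg$sex_mix, cfg$reporter_mix,
             cfg$region_mix, cfg$outcome_probs$dili,
             cfg$outcome_probs$non_dili, cfg$duplicate_rate,
             cfg$brand_variant_rate, cfg$concomitant_rate,
             cfg$extra_pt_rate, cfg$missing_date_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (mx in list(cfg$age_mix, cfg$sex_mix, cfg$reporter_mix,
                  cfg$region_mix, cfg$outcome_probs$dili,
                  cfg$outcome_probs$non_dili)) {
    if (!sums_to_1(mx)) stop("categorical distributions must sum to 1")
  }
  p0 <- cfg$background_dili_prob
  if (!(p0 > 0 && p0 < 1)) stop("background_dili_prob must be in (0, 1)")
  ror <- c(cfg$drug_ror, if (!is.null(cfg$stratum_ror)) cfg$stratum_ror$ror)
  if (any(ror <= 0)) stop("planted RORs must be positive")
  targets <- setdiff(names(cfg$drug_shares), "background")
  if (!all(targets %in% names(cfg$drug_ror))) {
    stop("drug_ror must cover every non-background drug")
  }
  need_mu <- c(targets, "background")
  if (!all(need_mu %in% names(cfg$onset_lognormal$mu))) {
    stop("onset_lognormal$mu must cover every drug and 'background'")
  }
  invisible(cfg)
}

#' Desk-scale configuration mirroring the published study
#'
#' Returns the default configuration at `n_cases = 50000`: expected per-drug
#' report counts proportional to the published distribution and planted RORs
#' equal to the published estimates, scaled for desk-speed end-to-end runs.
#'
#' @param seed RNG seed.
#' @return a `synthetic_config`.
#' @export
paper_scale_config <- function(seed = 1L) {
  synthetic_config(seed = seed, n_cases = 50000L)
}

# non-DILI reaction PT pool; disjoint from any plausible hepatic SMQ so
# classification in tests is unambiguous.
.nondili_pts <- c(
  "Nausea", "Headache", "Dizziness", "Myalgia", "Arthralgia", "Fatigue",
  "Rash", "Diarrhoea", "Dyspnoea", "Cough", "Insomnia", "Constipation",
  "Back pain", "Muscle spasms", "Pain in extremity", "Rhabdomyolysis",
  "Vomiting", "Pruritus", "Oedema peripheral", "Memory impairment",
  "Blood creatine phosphokinase increased", "Asthenia", "Vertigo",
  "Abdominal discomfort", "Tendon pain", "Hyperglycaemia", "Tremor",
  "Muscular weakness", "Chest pain", "Malaise"
)

.background_drugs <- c("METFORMIN", "OMEPRAZOLE", "LISINOPRIL",
                       "AMLODIPINE", "ASPIRIN", "IBUPROFEN", "SERTRALINE",
                       "LEVOTHYROXINE")

.region_countries <- list(
  north_america = c("US", "CA", "MX"),
  europe = c("FR", "DE", "GB", "IT", "ES", "NL", "SE", "CH", "PL"),
  asia = c("JP", "CN", "KR", "IN", "TH"),
  oceania = c("AU", "NZ"),
  south_america = c("BR", "AR", "CO", "CL"),
  africa = c("ZA", "NG", "EG", "KE"),
  unspecified = ""
)

#' Generate a synthetic five-table FAERS-like database with known truth
#'
#' Draws `n_cases` logical cases: a drug from `drug_shares`, DILI status from
#' the drug's planted odds (`ROR * p0 / (1 - p0)`, stratum-specific when
#' `stratum_ror` is given), demographics from the categorical mixes, one or
#' two reaction PTs (DILI cases from the SMQ term list, others from a
#' disjoint pool), at most one outcome, therapy start and event dates
#' consistent with a log-normal onset latency, and a receipt date in the
#' configured year span. A configurable fraction of cases additionally emit
#' a superseded report version (earlier receipt date and lower PRIMARYID, or
#' a receipt-date tie in hostile mode) so deduplication is exercised with a
#' known intended survivor. Statin names are emitted as brand/salt variants
#' at the configured rate.
#'
#' The returned `truth` ledger records the per-drug realised contingency
#' cells, the per-case assignments, the duplicate map and the planted onset
#' medians; pipeline results on the generated tables can be checked against
#' it exactly.
#'
#' @param config a `synthetic_config`.
#' @param smq an `smq_term_set` supplying the DILI PT vocabulary.
#' @param dict a `drug_dictionary` supplying brand/salt variants.
#' @return list with raw-format tibbles `demo`, `drug`, `reac`, `outc`,
#'   `ther` (FAERS column names, all-character) and `truth`.
#' @export
generate_faers <- function(config, smq = load_smq_terms(),
                           dict = load_drug_dictionary()) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_cases
  drugs_all <- names(config$drug_shares)
  drug <- sample(drugs_all, n, replace = TRUE,
                 prob = unname(config$drug_shares))
  age_group <- sample(names(config$age_mix), n, replace = TRUE,
                      prob = unname(config$age_mix))
  age <- rep(NA_integer_, n)
  age[age_group == "<65"] <- sample(18:64, sum(age_group == "<65"), TRUE)
  age[age_group == ">=65"] <- sample(65:95, sum(age_group == ">=65"), TRUE)

  # planted DILI odds per case
  ror <- rep(1, n)
  idx <- drug != "background"
  ror[idx] <- unname(config$drug_ror[drug[idx]])
  if (!is.null(config$stratum_ror)) {
    sr <- config$stratum_ror
    for (k in seq_len(nrow(sr))) {
      hit <- drug == sr$drug[k] & age_group == sr$age_group[k]
      ror[hit] <- sr$ror[k]
    }
  }
  q0 <- config$background_dili_prob / (1 - config$background_dili_prob)
  odds <- ror * q0
  p_dili <- odds / (1 + odds)
  dili <- runif(n) < p_dili

  sex_code <- c(female = "F", male = "M", unknown = "")[
    sample(names(config$sex_mix), n, TRUE, unname(config$sex_mix))]
  occp_code <- c(health_professional = "MD", non_health_professional = "CN",
                 unknown = "")[
    sample(names(config$reporter_mix), n, TRUE,
           unname(config$reporter_mix))]
  region <- sample(names(config$region_mix), n, TRUE,
                   unname(config$region_mix))
  country <- unname(vapply(region, function(r) {
    pool <- .region_countries[[r]]
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1)))

  year <- sample(seq(config$year_range[1], config$year_range[2]), n, TRUE)
  fda_date <- as.Date(sprintf("%d-01-01", year)) +
    sample(0:364, n, TRUE)
  onset <- pmax(0, round(rlnorm(n, config$onset_lognormal$mu[drug],
                                config$onset_lognormal$sigma)))
  event_date <- fda_date - sample(0:90, n, TRUE)
  start_date <- event_date - onset

  degrade <- function(pd_full) {
    u <- runif(n)
    out <- pd_full
    hit <- u < config$missing_date_rate
    kind <- runif(n)
    out[hit & kind < 0.5] <- NA_character_
    out[hit & kind >= 0.5 & kind < 0.75] <-
      substr(pd_full[hit & kind >= 0.5 & kind < 0.75], 1, 6)
    out[hit & kind >= 0.75] <- substr(pd_full[hit & kind >= 0.75], 1, 4)
    out
  }
  event_pd <- degrade(format(event_date, "%Y%m%d"))
  start_pd <- degrade(format(start_date, "%Y%m%d"))

  # reactions
  pt1 <- ifelse(dili, sample(smq$terms, n, TRUE),
                sample(.nondili_pts, n, TRUE))
  extra <- runif(n) < config$extra_pt_rate
  pt2 <- rep(NA_character_, n)
  pt2[extra & dili] <- sample(smq$terms, sum(extra & dili), TRUE)
  pt2[extra & !dili] <- sample(.nondili_pts, sum(extra & !dili), TRUE)

  # outcomes (at most one per case)
  out_codes <- names(config$outcome_probs$dili)
  outcome <- rep(NA_character_, n)
  outcome[dili] <- sample(out_codes, sum(dili), TRUE,
                          unname(config$outcome_probs$dili))
  outcome[!dili] <- sample(out_codes, sum(!dili), TRUE,
                           unname(config$outcome_probs$non_dili))
  outcome[outcome == "none"] <- NA_character_

  # drug names: brand/salt variants drawn from the dictionary fixture
  variants <- lapply(setNames(statin_generics, statin_generics), function(g) {
    keys <- names(dict$entries)[dict$entries == g]
    unique(c(setdiff(keys, toupper(g)), paste(toupper(g), "CALCIUM")))
  })
  raw_name <- toupper(drug)
  raw_name[!idx] <- sample(.background_drugs, sum(!idx), TRUE)
  use_variant <- idx & runif(n) < config$brand_variant_rate
  if (any(use_variant)) {
    raw_name[use_variant] <- vapply(drug[use_variant], function(g) {
      pool <- variants[[g]]
      if (length(pool)) sample(pool, 1) else toupper(g)
    }, character(1))
  }
  dose_amt <- rep(NA_real_, n)
  dose_amt[idx] <- sample(c(10, 20, 40, 80), sum(idx), TRUE,
                          prob = c(0.22, 0.24, 0.25, 0.29))

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"), event_dt = event_pd,
    age = ifelse(is.na(age), NA_character_, as.character(age)),
    age_cod = ifelse(is.na(age), NA_character_, "YR"),
    sex = sex_code, occp_cod = occp_code, occr_country = country
  )
  drug_tbl <- tibble::tibble(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = raw_name,
    dose_amt = ifelse(is.na(dose_amt), NA_character_,
                      as.character(dose_amt)),
    dose_unit = ifelse(is.na(dose_amt), NA_character_, "MG"),
    dose_freq = ifelse(is.na(dose_amt), NA_character_, "QD")
  )
  conc <- runif(n) < config$concomitant_rate
  if (any(conc)) {
    drug_tbl <- dplyr::bind_rows(drug_tbl, tibble::tibble(
      primaryid = primaryid[conc], drug_seq = "2", role_cod = "C",
      drugname = "PARACETAMOL", dose_amt = NA_character_,
      dose_unit = NA_character_, dose_freq = NA_character_
    ))
  }
  reac <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid, pt = pt1),
    tibble::tibble(primaryid = primaryid[extra], pt = pt2[extra])
  )
  has_out <- !is.na(outcome)
  outc <- tibble::tibble(primaryid = primaryid[has_out],
                         outc_cod = outcome[has_out])
  has_start <- !is.na(start_pd)
  ther <- tibble::tibble(primaryid = primaryid[has_start],
                         dsg_drug_seq = "1", start_dt = start_pd[has_start])

  # superseded report versions: earlier receipt date (or a tie in hostile
  # mode) and a lower primaryid, so the intended survivor is known.
  dup <- runif(n) < config$duplicate_rate
  if (any(dup)) {
    old_pid <- paste0(caseid[dup], "1")
    old_fda <- if (config$hostile_ties) fda_date[dup] else
      fda_date[dup] - sample(10:200, sum(dup), TRUE)
    copy_rows <- function(tbl, pid_new) {
      sub <- tbl[tbl$primaryid %in% primaryid[dup], ]
      sub$primaryid <- pid_new[match(sub$primaryid, primaryid[dup])]
      sub
    }
    demo_old <- demo[dup, ]
    demo_old$primaryid <- old_pid
    demo_old$fda_dt <- format(old_fda, "%Y%m%d")
    demo <- dplyr::bind_rows(demo, demo_old)
    drug_tbl <- dplyr::bind_rows(drug_tbl, copy_rows(drug_tbl, old_pid))
    reac <- dplyr::bind_rows(reac, copy_rows(reac, old_pid))
    outc <- dplyr::bind_rows(outc, copy_rows(outc, old_pid))
    ther <- dplyr::bind_rows(ther, copy_rows(ther, old_pid))
  }

  targets <- setdiff(drugs_all, "background")
  cells <- lapply(setNames(targets, targets), function(dg) {
    on <- drug == dg
    list(a = sum(on & dili), b = sum(on & !dili),
         c = sum(!on & dili), d = sum(!on & !dili))
  })
  truth <- list(
    config = config,
    cells = cells,
    assignments = tibble::tibble(
      caseid = caseid, primaryid = primaryid, drug = drug, dili = dili,
      age_group = age_group, onset_days = onset,
      receipt_year = year
    ),
    duplicate_map = {
      dup_caseid <- caseid[dup]
      tibble::tibble(caseid = dup_caseid,
                     removed_primaryid = paste0(dup_caseid, "1"),
                     survivor_primaryid = primaryid[dup])
    },
    planted_onset_median = exp(config$onset_lognormal$mu),
    n_cases = n,
    n_duplicates = sum(dup)
  )
  list(demo = demo, drug = drug_tbl, reac = reac, outc = outc, ther = ther,
       truth = truth)
}

#' Write a generated database as FAERS-style files
#'
#' Emits the five "$"-delimited text files (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `OUTC.txt`, `THER.txt`) that [read_faers_dir()] reads, plus
#' `truth.json` with the ledger's cells and bookkeeping counts.
#'
#' @param db output of [generate_faers()].
#' @param dir destination directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_faers_tables <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".txt"))
    m <- as.matrix(tbl)
    m[is.na(m)] <- ""
    body <- if (nrow(m)) apply(m, 1, paste, collapse = "$") else character(0)
    lines <- c(paste(colnames(m), collapse = "$"), body)
    writeLines(lines, p)
    p
  }
  paths <- c(
    emit(db$demo, "DEMO"), emit(db$drug, "DRUG"), emit(db$reac, "REAC"),
    emit(db$outc, "OUTC"), emit(db$ther, "THER")
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(cells = db$truth$cells, n_cases = db$truth$n_cases,
         n_duplicates = db$truth$n_duplicates,
         planted_onset_median = as.list(db$truth$planted_onset_median)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth_path))
}
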