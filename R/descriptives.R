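#' Reported proportion, half-up at two decimals
#'
#' @param numerator,denominator nonnegative counts (`numerator <=
#'   denominator`, `denominator > 0`; a zero denominator returns `NA`).
#' @return percentage rounded half-up to 2 decimals.
#' @examples
#' proportion(4160, 7779)  # 53.48
#' @export
proportion <- function(numerator, denominator) {
  out <- ifelse(denominator > 0, 100 * numerator / denominator, NA_real_)
  round_half_up(out, 2)
}

# label lookups for the rollup tables
.outcome_labels <- c(DE = "Death", LT = "Life threatening",
                     HO = "Hospitalization", DS = "Disability",
                     CA = "Congenital anomaly", RI = "Required intervention",
                     OT = "Other serious events")
.region_labels <- c(north_america = "North America", europe = "Europe",
                    asia = "Asian", oceania = "Oceania",
                    south_america = "South America", africa = "Africa",
                    unspecified = "Unspecified")

#' Demographic and outcome rollups for DILI vs non-DILI statin cases
#'
#' Produces the standard descriptive comparison of statin-exposed DILI and
#' non-DILI cases: counts and percentages per statin, age group (`<65`,
#' `>=65`, unknown), sex, outcome, reporter occupation and reporter region.
#' Denominators are the group totals; Unknown rows are always emitted, never
#' silently dropped. Statin rows count a multi-statin case once per statin;
#' outcome rows count a case once per distinct outcome code, with "Unknown"
#' for cases reporting none.
#'
#' @param cohort a `dili_cohort`.
#' @return tibble with columns `characteristic`, `category`, `dili_n`,
#'   `dili_pct`, `nondili_n`, `nondili_pct`.
#' @export
demographics_table <- function(cohort) {
  cases <- cohort$cases[cohort$cases$has_statin, ]
  dili <- cases[cases$is_dili, ]
  nond <- cases[!cases$is_dili, ]
  n_d <- nrow(dili)
  n_n <- nrow(nond)

  count_level <- function(vals, levels) {
    tab <- table(factor(vals, levels = levels))
    as.integer(tab)
  }
  block <- function(characteristic, levels, dili_vals, nond_vals,
                    labels = NULL) {
    dn <- count_level(dili_vals, levels)
    nn <- count_level(nond_vals, levels)
    tibble::tibble(
      characteristic = characteristic,
      category = if (is.null(labels)) levels else unname(labels[levels]),
      dili_n = dn, dili_pct = proportion(dn, n_d),
      nondili_n = nn, nondili_pct = proportion(nn, n_n)
    )
  }
  statins_of <- function(df) unlist(df$statins)
  outcomes_of <- function(df) {
    o <- df$outcomes
    o[lengths(o) == 0] <- list("Unknown")
    unlist(o)
  }
  sex_levels <- c("female", "male", "unknown")
  sex_labels <- c(female = "Female", male = "Male", unknown = "Unknown")
  rep_levels <- c("health_professional", "non_health_professional", "unknown")
  rep_labels <- c(health_professional = "Health-professional",
                  non_health_professional = "Non-health professionals",
                  unknown = "Unknown")
  age_levels <- c("<65", ">=65", "unknown")
  age_labels <- c("<65" = "< 65 years", ">=65" = ">= 65 years",
                  unknown = "Unknown")
  out_levels <- c(names(.outcome_labels), "Unknown")
  out_labels <- c(.outcome_labels, Unknown = "Unknown")

  dplyr::bind_rows(
    block("statin", statin_generics, statins_of(dili), statins_of(nond),
          setNames(tools::toTitleCase(statin_generics), statin_generics)),
    block("age_group", age_levels, dili$age_group, nond$age_group,
          age_labels),
    block("sex", sex_levels, dili$sex, nond$sex, sex_labels),
    block("outcome", out_levels, outcomes_of(dili), outcomes_of(nond),
          out_labels),
    block("reporter", rep_levels, dili$reporter, nond$reporter, rep_labels),
    block("region", names(.region_labels), dili$region, nond$region,
          .region_labels)
  )
}

#' Pearson chi-square test for a frequency table
#'
#' Pearson's chi-square without continuity correction on an r x c table of
#' counts, `df = (r - 1)(c - 1)`. Any all-zero row or column (zero expected
#' cell) is a hard error naming the offending margin — degenerate tables must
#' be collapsed by the caller, not silently patched.
#'
#' @param counts matrix (or coercible data frame) of nonnegative counts with
#'   at least 2 rows and 2 columns.
#' @return named list `statistic`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) stop("chi_square needs a >= 2 x 2 table")
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0)) stop("expected cell count 0: all-zero row ",
                         which(rs == 0)[1])
  if (any(cs == 0)) stop("expected cell count 0: all-zero column ",
                         which(cs == 0)[1])
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Dose-group distribution and trend for one statin
#'
#' Rolls the target drug's cases up by daily dose (mg/day) and tests both
#' heterogeneity (Pearson chi-square on the DILI x dose table) and a
#' monotone dose-response trend in the DILI proportion (Cochran-Armitage via
#' [stats::prop.trend.test()], scored by dose). Cases whose dose is missing,
#' unparseable or outside `dose_levels` are excluded and counted.
#'
#' @param cohort a `dili_cohort`.
#' @param drug target generic (default `"atorvastatin"`, the statin with a
#'   published dose-response finding).
#' @param dose_levels daily-dose groups in mg (default 10/20/40/80).
#' @return list: `table` (tibble `dose_mg`, `dili_n`, `nondili_n`,
#'   `dili_pct`), `chisq` (heterogeneity test or `NULL`), `trend_p`
#'   (`NA` when undefined), `n_excluded`.
#' @export
dose_trend <- function(cohort, drug = "atorvastatin",
                       dose_levels = c(10, 20, 40, 80)) {
  exp <- cohort$exposures[cohort$exposures$generic == drug, ]
  cases <- cohort$cases[c("primaryid", "is_dili")]
  df <- dplyr::inner_join(exp, cases, by = "primaryid")
  in_grp <- !is.na(df$dose_per_day_mg) & df$dose_per_day_mg %in% dose_levels
  n_excluded <- sum(!in_grp)
  df <- df[in_grp, ]
  dose <- factor(df$dose_per_day_mg, levels = dose_levels)
  dili_n <- as.integer(table(dose[df$is_dili]))
  nond_n <- as.integer(table(dose[!df$is_dili]))
  tab <- tibble::tibble(dose_mg = dose_levels, dili_n = dili_n,
                        nondili_n = nond_n,
                        dili_pct = proportion(dili_n, dili_n + nond_n))
  totals <- dili_n + nond_n
  occupied <- totals > 0
  if (sum(occupied) < 2 || sum(dili_n) == 0) {
    return(list(table = tab, chisq = NULL, trend_p = NA_real_,
                n_excluded = n_excluded))
  }
  m <- rbind(dili_n[occupied], nond_n[occupied])
  chisq <- if (all(rowSums(m) > 0)) chi_square(m) else NULL
  # suppressed: prop.trend.test warns on perfectly flat profiles, where the
  # trend statistic is legitimately ~0
  trend <- suppressWarnings(
    stats::prop.trend.test(dili_n[occupied], totals[occupied],
                           score = dose_levels[occupied]))
  list(table = tab, chisq = chisq, trend_p = trend$p.value,
       n_excluded = n_excluded)
}

#' Days from therapy start to event
#'
#' Defined only when both dates carry day precision and the difference is
#' nonnegative; anything else is `NA` (the case drops out of the onset
#' analysis and is counted by the caller).
#'
#' @param event_dt,start_dt canonical partial dates (vectors, recycled).
#' @return integer vector of days, `NA` where undefined.
#' @export
onset_days <- function(event_dt, start_dt) {
  ev <- pd_as_date(event_dt)
  st <- pd_as_date(start_dt)
  out <- as.integer(ev - st)
  out[is.na(out) | out < 0] <- NA_integer_
  out
}

#' Extract per-drug time-to-onset samples
#'
#' One onset sample per (DILI case, statin) pair with a defined onset; a case
#' with several PS statins contributes to each of its statins.
#'
#' @param cohort a `dili_cohort`.
#' @return tibble `drug`, `onset_days`.
#' @export
onset_samples <- function(cohort) {
  cases <- cohort$cases[cohort$cases$has_statin & cohort$cases$is_dili &
                          !is.na(cohort$cases$onset_days), ]
  if (nrow(cases) == 0) {
    return(tibble::tibble(drug = character(0), onset_days = integer(0)))
  }
  tibble::tibble(
    drug = unlist(cases$statins),
    onset_days = rep(cases$onset_days, lengths(cases$statins))
  )
}

#' Per-drug onset medians and interquartile ranges
#'
#' Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7). Drugs without samples are absent from the
#' output; the pooled row is labelled `"all"`.
#'
#' @param samples tibble `drug`, `onset_days` (see [onset_samples()]).
#' @return tibble `drug`, `n`, `median_days`, `q1_days`, `q3_days`.
#' @export
onset_summary <- function(samples) {
  per_drug <- samples |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_days = unname(quantile(.data$onset_days, 0.5, type = 7)),
      q1_days = unname(quantile(.data$onset_days, 0.25, type = 7)),
      q3_days = unname(quantile(.data$onset_days, 0.75, type = 7)),
      .groups = "drop"
    )
  if (nrow(samples) > 0) {
    overall <- tibble::tibble(
      drug = "all", n = nrow(samples),
      median_days = unname(quantile(samples$onset_days, 0.5, type = 7)),
      q1_days = unname(quantile(samples$onset_days, 0.25, type = 7)),
      q3_days = unname(quantile(samples$onset_days, 0.75, type = 7))
    )
    per_drug <- dplyr::bind_rows(per_drug, overall)
  }
  per_drug
}

#' Compare time to onset across drugs
#'
#' One-way ANOVA of onset days across drugs (the conventional published
#' choice even on skewed latency data) plus all pairwise Welch two-sample
#' t-tests, uncorrected by default to match how raw pairwise p-values are
#' reported; a Kruskal-Wallis rank-based alternative is returned alongside
#' for sensitivity. Groups with fewer than 2 samples are dropped with a log
#' message; fewer than 2 usable groups yields `NA` results.
#'
#' @param samples tibble `drug`, `onset_days`.
#' @param p_adjust multiplicity correction for the pairwise tests (a
#'   [stats::p.adjust()] method; default `"none"`).
#' @return list: `anova_f`, `anova_p`, `kruskal_p`, `pairwise` (tibble
#'   `drug1`, `drug2`, `p`, `significant`), `dropped_groups`.
#' @export
compare_onset <- function(samples, p_adjust = "none") {
  sizes <- table(samples$drug)
  keep <- names(sizes)[sizes >= 2]
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    pv_log("compare_onset: dropping group(s) with < 2 samples: %s",
           paste(dropped, collapse = ", "))
  }
  df <- samples[samples$drug %in% keep, ]
  if (length(keep) < 2) {
    return(list(anova_f = NA_real_, anova_p = NA_real_,
                kruskal_p = NA_real_,
                pairwise = tibble::tibble(drug1 = character(0),
                                          drug2 = character(0),
                                          p = numeric(0),
                                          significant = logical(0)),
                dropped_groups = dropped))
  }
  df$drug <- factor(df$drug)
  fit <- aov(onset_days ~ drug, data = df)
  an <- summary(fit)[[1]]
  kw <- stats::kruskal.test(onset_days ~ drug, data = df)
  pw <- stats::pairwise.t.test(df$onset_days, df$drug, pool.sd = FALSE,
                               p.adjust.method = p_adjust)
  pm <- pw$p.value
  pairs <- tibble::tibble(
    drug1 = rep(rownames(pm), ncol(pm)),
    drug2 = rep(colnames(pm), each = nrow(pm)),
    p = as.vector(pm)
  )
  pairs <- pairs[!is.na(pairs$p), ]
  pairs$significant <- pairs$p < 0.05
  list(anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       kruskal_p = kw$p.value, pairwise = pairs, dropped_groups = dropped)
}

#' Annual DILI and non-DILI counts
#'
#' Counts statin-exposed cases per receipt year over a complete year range
#' (zeros for empty years).
#'
#' @param cohort a `dili_cohort`.
#' @param years integer year range; defaults to the span observed in the
#'   cohort.
#' @return tibble `year`, `dili_n`, `nondili_n`.
#' @export
annual_counts <- function(cohort, years = NULL) {
  cases <- cohort$cases[cohort$cases$has_statin, ]
  if (is.null(years)) {
    years <- if (nrow(cases) == 0) integer(0) else
      seq(min(cases$receipt_year), max(cases$receipt_year))
  }
  yr <- factor(cases$receipt_year, levels = years)
  tibble::tibble(
    year = as.integer(years),
    dili_n = as.integer(table(yr[cases$is_dili])),
    nondili_n = as.integer(table(yr[!cases$is_dili]))
  )
}
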