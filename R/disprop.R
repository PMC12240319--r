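#' Build the drug x DILI 2x2 contingency table
#'
#' Cells follow the standard disproportionality layout: `a` target drug &
#' DILI, `b` target drug & non-DILI, `c` all other reports & DILI, `d` all
#' other reports & non-DILI. The comparator is every case in the loaded
#' universe not exposed to the target drug as primary suspect; a case with
#' several PS statins counts on the target side whenever the target is among
#' them. When the loaded universe is a statin-only extract rather than a full
#' database, estimates are relative to that universe — the pipeline warns in
#' that situation because whole-database comparators give systematically
#' different baselines.
#'
#' @param cohort a `dili_cohort`, or a list with `cases` (`primaryid`,
#'   `is_dili`) and `exposures` (`primaryid`, `generic`).
#' @param drug target generic name.
#' @return list of class `contingency_table` with integer cells `a`, `b`,
#'   `c`, `d`, plus `n` and `drug`.
#' @export
build_contingency <- function(cohort, drug) {
  cases <- cohort$cases
  target_ids <- unique(cohort$exposures$primaryid[
    cohort$exposures$generic == drug])
  on_target <- cases$primaryid %in% target_ids
  a <- sum(on_target & cases$is_dili)
  b <- sum(on_target & !cases$is_dili)
  cc <- sum(!on_target & cases$is_dili)
  d <- sum(!on_target & !cases$is_dili)
  structure(list(a = a, b = b, c = cc, d = d, n = a + b + cc + d,
                 drug = drug),
            class = "contingency_table")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a/b) / (c/d)`; the interval is the Woolf log-scale interval
#' `exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`, with no continuity
#' correction. Any zero cell leaves the estimate undefined (`NA`): rather
#' than patching zero cells, the downstream signal rule fails such drugs via
#' its minimum-case criterion. An optional Haldane-style `+0.5` correction is
#' available for exploratory use.
#'
#' @param tab a `contingency_table` or list with `a`, `b`, `c`, `d`.
#' @param haldane add 0.5 to every cell before estimation (default `FALSE`).
#' @return named list `ror`, `ror_l`, `ror_u` (all `NA` when undefined).
#' @export
ror_estimate <- function(tab, haldane = FALSE) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (haldane) cells <- cells + 0.5
  if (any(cells == 0) || anyNA(cells)) {
    return(list(ror = NA_real_, ror_l = NA_real_, ror_u = NA_real_))
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  ror <- (a / b) / (cc / d)
  half <- 1.96 * sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(ror = ror, ror_l = ror * exp(-half), ror_u = ror * exp(half))
}

#' Information component with 95% credibility bounds
#'
#' The point estimate is the unshrunk observed-over-expected log ratio in
#' bits, `IC = log2(a * N / ((a + b) * (a + c)))` — the expected count under
#' independence being `(a + b) * (a + c) / N`. The optional `shrinkage` flag
#' applies the BCPNN-style `+0.5` stabilisation (`log2((a + 0.5) /
#' (E + 0.5))`); it is off by default. Interval methods, both shipped as
#' approximations:
#' * `"noren"`: the published asymmetric approximation
#'   `IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}` (lower) and
#'   `IC + 2.4 (a+0.5)^{-1/2} + 0.5 (a+0.5)^{-3/2}` (upper);
#' * `"gamma"`: `log2` of the 2.5th/97.5th percentiles of a
#'   `Gamma(a + 0.5, rate = E + 0.5)` posterior for the observed/expected
#'   ratio.
#'
#' @param tab a `contingency_table` or list with `a`, `b`, `c`, `d`.
#' @param ci_method `"noren"` (default) or `"gamma"`.
#' @param shrinkage apply `+0.5` stabilisation to the point estimate.
#' @return named list `ic`, `ic_l`, `ic_u`, `ic_ci_method`.
#' @export
ic_estimate <- function(tab, ci_method = c("noren", "gamma"),
                        shrinkage = FALSE) {
  ci_method <- match.arg(ci_method)
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  cc <- as.numeric(tab$c); d <- as.numeric(tab$d)
  n <- a + b + cc + d
  expected <- (a + b) * (a + cc) / n
  if (is.na(a) || a == 0 || is.na(expected) || expected == 0) {
    return(list(ic = NA_real_, ic_l = NA_real_, ic_u = NA_real_,
                ic_ci_method = ci_method))
  }
  ic <- if (shrinkage) log2((a + 0.5) / (expected + 0.5)) else
    log2(a / expected)
  if (ci_method == "noren") {
    s <- a + 0.5
    ic_l <- ic - 3.3 * s^(-0.5) - 2 * s^(-1.5)
    ic_u <- ic + 2.4 * s^(-0.5) + 0.5 * s^(-1.5)
  } else {
    qs <- qgamma(c(0.025, 0.975), shape = a + 0.5, rate = expected + 0.5)
    ic_l <- log2(qs[1])
    ic_u <- log2(qs[2])
  }
  list(ic = ic, ic_l = ic_l, ic_u = ic_u, ic_ci_method = ci_method)
}

#' Apply the dual signal criteria
#'
#' A drug-event pair is a signal only when both disproportionality rules
#' fire: the frequentist rule (at least 3 reported cases and ROR 95% CI lower
#' limit above 1) and the Bayesian rule (IC above 1 and credibility lower
#' bound above 0). Undefined estimates (`NA`) fail the corresponding rule.
#'
#' @param n_cases number of target-drug DILI reports (= cell `a`).
#' @param ror_l ROR 95% CI lower limit.
#' @param ic IC point estimate (bits).
#' @param ic_l IC credibility lower bound.
#' @return named logical list `ror_signal`, `ic_signal`, `signal`
#'   (vectorised over the inputs).
#' @export
classify_signal <- function(n_cases, ror_l, ic, ic_l) {
  ror_signal <- !is.na(ror_l) & n_cases >= 3 & ror_l > 1
  ic_signal <- !is.na(ic) & !is.na(ic_l) & ic > 1 & ic_l > 0
  list(ror_signal = ror_signal, ic_signal = ic_signal,
       signal = ror_signal & ic_signal)
}

#' Per-drug disproportionality signal table
#'
#' Builds the 2x2 table for each target drug against the loaded universe and
#' computes ROR, IC, intervals and the dual-criterion decision.
#'
#' @param cohort a `dili_cohort`.
#' @param drugs target generics (default all eight statins).
#' @param stratum optional stratum label recorded in the output.
#' @param ic_ci_method IC interval method, see [ic_estimate()].
#' @param warn_universe warn when the universe looks like a statin-only
#'   extract (no unexposed comparator cases).
#' @return tibble, one row per drug: `drug`, `stratum`, `a`, `b`, `c`, `d`,
#'   `ror`, `ror_l`, `ror_u`, `ic`, `ic_l`, `ic_u`, `n_cases`, `ror_signal`,
#'   `ic_signal`, `signal`, `ic_ci_method`.
#' @export
signal_table <- function(cohort, drugs = statin_generics, stratum = NA,
                         ic_ci_method = c("noren", "gamma"),
                         warn_universe = TRUE) {
  ic_ci_method <- match.arg(ic_ci_method)
  if (warn_universe && all(cohort$cases$has_statin)) {
    warning("universe contains only statin-exposed cases; ROR/IC are ",
            "relative to the loaded statin extract, not a full database",
            call. = FALSE)
  }
  rows <- lapply(drugs, function(dg) {
    tab <- build_contingency(cohort, dg)
    r <- ror_estimate(tab)
    bayes <- ic_estimate(tab, ci_method = ic_ci_method)
    cls <- classify_signal(tab$a, r$ror_l, bayes$ic, bayes$ic_l)
    tibble::tibble(
      drug = dg, stratum = as.character(stratum),
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      ror = r$ror, ror_l = r$ror_l, ror_u = r$ror_u,
      ic = bayes$ic, ic_l = bayes$ic_l, ic_u = bayes$ic_u,
      n_cases = tab$a,
      ror_signal = cls$ror_signal, ic_signal = cls$ic_signal,
      signal = cls$signal, ic_ci_method = bayes$ic_ci_method
    )
  })
  dplyr::bind_rows(rows)
}

#' Age-stratified signal tables
#'
#' Rebuilds the per-drug tables within each age stratum (`<65`, `>=65`
#' years, boundary at 65 inclusive in the elderly group). Cases of unknown
#' age are excluded from both strata (they remain in the overall analysis);
#' the comparator is restricted to the same stratum. An empty stratum yields
#' no rows and a log message.
#'
#' @inheritParams signal_table
#' @return tibble as [signal_table()], with `stratum` set to `"<65"` or
#'   `">=65"`.
#' @export
stratified_signals <- function(cohort, drugs = statin_generics,
                               ic_ci_method = c("noren", "gamma")) {
  ic_ci_method <- match.arg(ic_ci_method)
  out <- list()
  for (st in c("<65", ">=65")) {
    idx <- cohort$cases$age_group == st
    if (!any(idx)) {
      pv_log("stratum %s is empty; skipped", st)
      next
    }
    sub <- list(cases = cohort$cases[idx, ],
                exposures = filter_to_primaryids(
                  cohort$exposures, cohort$cases$primaryid[idx]))
    out[[st]] <- signal_table(sub, drugs = drugs, stratum = st,
                              ic_ci_method = ic_ci_method,
                              warn_universe = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Recover the comparator background odds from printed summary rows
#'
#' Published disproportionality tables print, per drug, the DILI count `a`,
#' the total report count context (`b`) and the ROR — but not the comparator
#' cells `c` and `d`. Since `ROR = (a/b) / q` with `q = c/d` shared across
#' drugs, `q` is identifiable from the printed rows: this routine finds the
#' `q` minimising the sum of squared relative errors between `(a/b)/q` and
#' the printed RORs (closed form, since the objective is quadratic in `1/q`).
#' Used to cross-predict held-out drugs' printed statistics.
#'
#' @param printed data frame with columns `a`, `b`, `ror` (and optionally
#'   `drug`).
#' @param holdout optional drug name(s) to leave out of the fit.
#' @return list: `q` (comparator DILI odds `c/d`), `p` (= `q/(1+q)`,
#'   comparator DILI proportion), `n_drugs`, `residuals` (per-drug relative
#'   errors of the fit).
#' @export
recover_background <- function(printed, holdout = NULL) {
  tbl <- as.data.frame(printed)
  if (!is.null(holdout) && "drug" %in% names(tbl)) {
    tbl <- tbl[!(tbl$drug %in% holdout), ]
  }
  if (nrow(tbl) < 1) stop("recover_background: no rows left to fit")
  if (any(tbl$b == 0)) stop("recover_background: degenerate row with b = 0")
  r <- tbl$a / tbl$b
  # minimise sum_i ((r_i / q - R_i) / R_i)^2 over q; quadratic in x = 1/q
  q <- sum(r^2 / tbl$ror^2) / sum(r / tbl$ror)
  list(q = q, p = q / (1 + q), n_drugs = nrow(tbl),
       residuals = setNames((r / q - tbl$ror) / tbl$ror,
                            tbl$drug %||% NULL))
}
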