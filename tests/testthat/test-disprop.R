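test_that("contingency cells enumerate the universe correctly", {
  u <- mk_universe(drug = c("x", "x", "y", "y"),
                   dili = c(TRUE, FALSE, TRUE, FALSE))
  tab <- build_contingency(u, "x")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  # absent drug: degenerate but valid table
  tab <- build_contingency(u, "z")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(0, 0, 2, 2))
  # multi-exposure case counts on the target side once
  u2 <- list(
    cases = tibble::tibble(primaryid = c("p1", "p2"),
                           is_dili = c(TRUE, FALSE),
                           has_statin = TRUE),
    exposures = tibble::tibble(primaryid = c("p1", "p1", "p2"),
                               generic = c("x", "y", "y"))
  )
  tab <- build_contingency(u2, "x")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 0, 0, 1))
})

test_that("ROR point and Woolf interval match hand-evaluated values", {
  r <- ror_estimate(list(a = 10, b = 90, c = 100, d = 900))
  expect_equal(r$ror, 1.0)
  r <- ror_estimate(list(a = 20, b = 80, c = 10, d = 90))
  expect_equal(r$ror, 2.25)
  # half-width 1.96 * sqrt(1/20 + 1/80 + 1/10 + 1/90) = 0.816667
  expect_equal(r$ror_l, 2.25 * exp(-0.8166667), tolerance = 1e-6)
  expect_equal(r$ror_u, 2.25 * exp(0.8166667), tolerance = 1e-6)
  # zero cell: undefined marker, no Haldane patching by default
  r <- ror_estimate(list(a = 0, b = 10, c = 5, d = 100))
  expect_true(all(is.na(c(r$ror, r$ror_l, r$ror_u))))
  expect_false(is.na(ror_estimate(list(a = 0, b = 10, c = 5, d = 100),
                                  haldane = TRUE)$ror))
})

test_that("IC is the unshrunk log2 observed-over-expected", {
  # a+b = 100, a+c = 200, N = 10000 -> expected 2, observed 8 -> 2 bits
  tab <- list(a = 8, b = 92, c = 192, d = 9708)
  expect_equal(ic_estimate(tab)$ic, 2)
  # observed equal to expected -> 0 bits
  tab <- list(a = 10, b = 90, c = 90, d = 810)
  expect_equal(ic_estimate(tab)$ic, 0)
  # a = 0 -> undefined
  expect_true(is.na(ic_estimate(list(a = 0, b = 5, c = 5, d = 50))$ic))
  # shrinkage flag changes the point estimate
  tab <- list(a = 8, b = 92, c = 192, d = 9708)
  expect_equal(ic_estimate(tab, shrinkage = TRUE)$ic, log2(8.5 / 2.5))
})

test_that("both IC interval methods bracket the point estimate", {
  tab <- list(a = 169, b = 1415, c = 170000, d = 9830000)
  for (m in c("noren", "gamma")) {
    ic <- ic_estimate(tab, ci_method = m)
    expect_lt(ic$ic_l, ic$ic)
    expect_gt(ic$ic_u, ic$ic)
    expect_equal(ic$ic_ci_method, m)
  }
})

test_that("dual signal criteria require both rules and >= 3 cases", {
  cls <- classify_signal(n_cases = 169, ror_l = 5.89, ic = 2.65, ic_l = 2.08)
  expect_true(cls$signal)
  # IC rule fails (ic <= 1)
  cls <- classify_signal(n_cases = 52, ror_l = 1.43, ic = 0.89, ic_l = -0.04)
  expect_true(cls$ror_signal)
  expect_false(cls$ic_signal)
  expect_false(cls$signal)
  # minimum-case gate
  cls <- classify_signal(n_cases = 2, ror_l = 5, ic = 3, ic_l = 2)
  expect_false(cls$signal)
  # undefined estimates fail their rule
  cls <- classify_signal(n_cases = 10, ror_l = NA, ic = 3, ic_l = 2)
  expect_false(cls$ror_signal)
  expect_true(cls$ic_signal)
})

test_that("ROR is invariant to comparator scaling; CI tends to the 2-cell width", {
  base <- list(a = 20, b = 80, c = 100, d = 900)
  r0 <- ror_estimate(base)
  for (k in c(10, 1000)) {
    rk <- ror_estimate(list(a = 20, b = 80, c = 100 * k, d = 900 * k))
    expect_equal(rk$ror, r0$ror)
  }
  rbig <- ror_estimate(list(a = 20, b = 80, c = 1e8, d = 9e8))
  limit_half <- 1.96 * sqrt(1 / 20 + 1 / 80)
  expect_equal(log(rbig$ror_u / rbig$ror), limit_half, tolerance = 1e-4)
})

test_that("ROR and IC increase with the target-DILI cell", {
  prev_ror <- -Inf
  prev_ic <- -Inf
  for (a in c(5, 10, 20, 40)) {
    tab <- list(a = a, b = 100, c = 50, d = 1000)
    expect_gt(ror_estimate(tab)$ror, prev_ror)
    expect_gt(ic_estimate(tab)$ic, prev_ic)
    prev_ror <- ror_estimate(tab)$ror
    prev_ic <- ic_estimate(tab)$ic
  }
  # at independence both signals vanish together
  tab <- list(a = 10, b = 90, c = 90, d = 810)
  expect_equal(ror_estimate(tab)$ror, 1)
  expect_equal(ic_estimate(tab)$ic, 0)
})

test_that("background-odds recovery matches a brute-force 1-D minimiser", {
  printed <- printed_signal_table()
  fit <- printed[printed$drug %in% c("atorvastatin", "rosuvastatin",
                                     "simvastatin", "pravastatin"), ]
  bg <- recover_background(fit)
  # independent oracle: numeric minimisation of the same objective
  obj <- function(q) {
    sum(((fit$a / fit$b) / q - fit$ror)^2 / fit$ror^2)
  }
  q_opt <- stats::optimize(obj, c(1e-4, 1), tol = 1e-12)$minimum
  expect_equal(bg$q, q_opt, tolerance = 1e-6)
  expect_equal(bg$p, bg$q / (1 + bg$q))
  # single-point fit is exact: q = (a/b) / ROR
  one <- fit[1, ]
  expect_equal(recover_background(one)$q, (one$a / one$b) / one$ror)
  # joint fit over all eight rows leaves small per-drug residuals
  full <- recover_background(printed)
  expect_lt(max(abs(full$residuals)), 0.02)
  expect_error(recover_background(data.frame(a = 1, b = 0, ror = 2)),
               "b = 0")
})

test_that("holdout rows are excluded from the background fit", {
  printed <- printed_signal_table()
  bg_all <- recover_background(printed)
  bg_hold <- recover_background(printed, holdout = c("fluvastatin",
                                                     "cerivastatin"))
  expect_false(isTRUE(all.equal(bg_all$q, bg_hold$q)))
  expect_equal(bg_hold$n_drugs, 6)
})

test_that("stratified tables restrict target and comparator to the stratum", {
  cfg <- synthetic_config(
    seed = 31, n_cases = 30000,
    drug_shares = c(atorvastatin = 0.15, background = 0.85),
    drug_ror = c(atorvastatin = 2.0),
    stratum_ror = data.frame(drug = "atorvastatin",
                             age_group = c("<65", ">=65"),
                             ror = c(2.0, 4.0)),
    background_dili_prob = 0.05,
    age_mix = c("<65" = 0.45, ">=65" = 0.45, unknown = 0.1),
    duplicate_rate = 0, missing_date_rate = 0
  )
  db <- generate_faers(cfg)
  d <- withr::local_tempdir()
  write_faers_tables(db, d)
  co <- assemble_cohort(read_faers_dir(d), test_dict, test_smq)
  st <- stratified_signals(co, drugs = "atorvastatin")
  expect_setequal(st$stratum, c("<65", ">=65"))
  young <- st[st$stratum == "<65", ]
  old <- st[st$stratum == ">=65", ]
  # planted stratum RORs inside the estimated 95% CIs
  expect_gt(2.0, young$ror_l); expect_lt(2.0, young$ror_u)
  expect_gt(4.0, old$ror_l); expect_lt(4.0, old$ror_u)
  # unknown-age cases contribute to neither stratum
  n_known <- sum(co$cases$age_group != "unknown")
  expect_equal(sum(st$a + st$b + st$c + st$d), n_known)
  # age-65 boundary falls in the elderly stratum
  expect_equal(unique(co$cases$age_group[which(co$cases$age_years == 65)]),
               ">=65")
})
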