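test_that("reported proportions use half-up rounding at two decimals", {
  expect_equal(proportion(4160, 7779), 53.48)
  expect_equal(proportion(184, 1514), 12.15)
  expect_equal(proportion(0, 7779), 0)
  expect_equal(proportion(1, 800), 0.13)   # 0.125 rounds half-up
  expect_true(is.na(proportion(5, 0)))
})

test_that("chi-square matches hand-evaluated and brute-force values", {
  res <- chi_square(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p, 0.009823, tolerance = 1e-3)
  res <- chi_square(rbind(c(5, 5), c(5, 5)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res <- chi_square(rbind(c(30, 0), c(0, 30)))
  expect_equal(res$statistic, 60)
  expect_error(chi_square(rbind(c(0, 0), c(5, 5))), "row")
  expect_error(chi_square(cbind(c(0, 0), c(5, 5))), "column")
  # brute force sum((O-E)^2/E) on random tables
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(sample(1:50, 6, replace = TRUE), 2, 3)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chi_square(m)$statistic, sum((m - e)^2 / e),
                 tolerance = 1e-10)
  }
})

test_that("onset days require day precision on both dates and nonnegativity", {
  expect_equal(onset_days("20230301", "20230201"), 28L)
  expect_equal(onset_days("20230301", "20230301"), 0L)
  expect_true(is.na(onset_days("20230301", "202302")))
  expect_true(is.na(onset_days("202303", "20230201")))
  expect_true(is.na(onset_days("20230201", "20230301")))  # negative
  expect_true(is.na(onset_days(NA, "20230201")))
})

test_that("onset summaries use interpolated quartiles", {
  s <- tibble::tibble(drug = "x", onset_days = c(10L, 20L, 30L))
  out <- onset_summary(s)
  x <- out[out$drug == "x", ]
  expect_equal(c(x$median_days, x$q1_days, x$q3_days), c(20, 15, 25))
  one <- onset_summary(tibble::tibble(drug = "y", onset_days = 40L))
  expect_equal(one$median_days[one$drug == "y"], 40)
  expect_equal(one$q1_days[one$drug == "y"], 40)
  # permutation invariance and day->week scale equivariance
  set.seed(3)
  v <- sample(1:500, 41)
  a <- onset_summary(tibble::tibble(drug = "z", onset_days = v))
  b <- onset_summary(tibble::tibble(drug = "z", onset_days = sample(v)))
  expect_equal(a, b)
  w <- onset_summary(tibble::tibble(drug = "z", onset_days = v / 7))
  expect_equal(w$median_days, a$median_days / 7)
  expect_equal(w$q3_days, a$q3_days / 7)
})

test_that("onset comparison: identical groups are null, shifts are detected", {
  g <- rep(c(25, 30, 40, 55, 80), 10)
  s <- tibble::tibble(drug = rep(c("a", "b"), each = 50),
                      onset_days = c(g, g))
  res <- compare_onset(s)
  expect_gt(res$anova_p, 0.99)
  expect_equal(sum(res$pairwise$significant), 0)
  # planted multiplicative shift on the log scale
  set.seed(17)
  s <- tibble::tibble(
    drug = rep(c("a", "b"), each = 200),
    onset_days = round(c(rlnorm(200, log(25), 1), rlnorm(200, log(25) + 1, 1)))
  )
  res <- compare_onset(s)
  expect_lt(res$anova_p, 0.01)
  expect_lt(res$kruskal_p, 0.01)
  expect_true(all(res$pairwise$significant))
  # groups below 2 samples are dropped; < 2 usable groups is undefined
  s3 <- tibble::tibble(drug = c("a", "a", "a", "b"),
                       onset_days = c(5, 10, 20, 7))
  res <- compare_onset(s3)
  expect_equal(res$dropped_groups, "b")
  expect_true(is.na(res$anova_p))
})

test_that("dose trend detects planted monotone dose-response", {
  mk_cohort <- function(dili_n, nond_n) {
    doses <- c(10, 20, 40, 80)
    n <- sum(dili_n) + sum(nond_n)
    pid <- sprintf("p%04d", seq_len(n))
    dose <- c(rep(doses, dili_n), rep(doses, nond_n))
    dili <- rep(c(TRUE, FALSE), c(sum(dili_n), sum(nond_n)))
    list(
      cases = tibble::tibble(primaryid = pid, is_dili = dili,
                             has_statin = TRUE),
      exposures = tibble::tibble(primaryid = pid, generic = "atorvastatin",
                                 drug_seq = 1L, dose_per_day_mg = dose)
    )
  }
  # DILI share rising with dose
  res <- dose_trend(mk_cohort(c(40, 60, 90, 130), c(400, 380, 330, 280)))
  expect_lt(res$trend_p, 0.01)
  expect_equal(res$table$dili_n, c(40, 60, 90, 130))
  # flat profile: no trend
  res <- dose_trend(mk_cohort(rep(50, 4), rep(200, 4)))
  expect_gt(res$trend_p, 0.9)
  # single occupied group: undefined
  res <- dose_trend(mk_cohort(c(10, 0, 0, 0), c(40, 0, 0, 0)))
  expect_true(is.na(res$trend_p))
})

test_that("demographic rollups conserve group totals and keep Unknown rows", {
  cfg <- synthetic_config(seed = 13, n_cases = 3000)
  db <- generate_faers(cfg)
  d <- withr::local_tempdir()
  write_faers_tables(db, d)
  co <- assemble_cohort(read_faers_dir(d), test_dict, test_smq)
  tab <- demographics_table(co)
  n_dili <- co$report$n_statin_dili
  n_nond <- co$report$n_statin_cases - n_dili
  for (ch in c("age_group", "sex", "reporter", "region")) {
    sub <- tab[tab$characteristic == ch, ]
    expect_equal(sum(sub$dili_n), n_dili)
    expect_equal(sum(sub$nondili_n), n_nond)
  }
  expect_true(all(c("Unknown") %in% tab$category[tab$characteristic == "sex"]))
  # statin rows reconcile with the truth ledger cells (a and b per drug)
  for (g in c("atorvastatin", "simvastatin")) {
    cell <- db$truth$cells[[g]]
    row <- tab[tab$characteristic == "statin" &
                 tab$category == tools::toTitleCase(g), ]
    expect_equal(row$dili_n, cell$a)
    expect_equal(row$nondili_n, cell$b)
  }
})

test_that("annual counts emit a complete year range with zeros", {
  cfg <- synthetic_config(seed = 19, n_cases = 800,
                          year_range = c(2010L, 2012L))
  db <- generate_faers(cfg)
  d <- withr::local_tempdir()
  write_faers_tables(db, d)
  co <- assemble_cohort(read_faers_dir(d), test_dict, test_smq)
  ann <- annual_counts(co, years = 2009:2013)
  expect_equal(ann$year, 2009:2013)
  expect_equal(ann$dili_n[ann$year == 2009], 0)
  expect_equal(sum(ann$dili_n) + sum(ann$nondili_n),
               co$report$n_statin_cases)
  # ledger cross-check on receipt years of statin cases
  truth_years <- db$truth$assignments[
    db$truth$assignments$drug != "background", ]
  expect_equal(sum(ann$dili_n + ann$nondili_n),
               nrow(truth_years))
})
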