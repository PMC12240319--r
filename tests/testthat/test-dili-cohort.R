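test_that("SMQ classification collapses multiple matched terms to one case", {
  res <- classify_dili(c("Hepatitis", "Nausea"), test_smq)
  expect_true(res$is_dili)
  expect_equal(res$matched_pts, "Hepatitis")
  res <- classify_dili(c("Hepatitis", "Liver injury"), test_smq)
  expect_true(res$is_dili)
  expect_length(res$matched_pts, 2)   # one case, two matched terms
  res <- classify_dili("Headache", test_smq)
  expect_false(res$is_dili)
  expect_length(res$matched_pts, 0)
  # matching is case- and whitespace-insensitive
  expect_true(classify_dili("  liver   INJURY ", test_smq)$is_dili)
  # monotone: adding PTs never flips true -> false
  set.seed(1)
  for (i in 1:20) {
    base <- sample(test_smq$terms, 1)
    more <- c(base, sample(c("Nausea", "Headache", test_smq$terms), 3))
    expect_true(classify_dili(more, test_smq)$is_dili)
  }
})

test_that("an empty SMQ term set is a configuration error", {
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# nothing but comments", empty)
  expect_error(load_smq_terms(empty), "empty")
})

test_that("temporal exclusion drops only strictly-later starts", {
  expect_false(temporal_exclusion_keep("20230401", "20230501"))
  expect_true(temporal_exclusion_keep("20230401", "20230401"))
  expect_true(temporal_exclusion_keep("20230401", "20230301"))
  # coarse precision: 2023 vs 2023-03-15 is not strictly later
  expect_true(temporal_exclusion_keep("20230315", "2023"))
  expect_false(temporal_exclusion_keep("202302", "20230315"))  # Mar > Feb
  # missing information never excludes
  expect_true(temporal_exclusion_keep(NA, "20230501"))
  expect_true(temporal_exclusion_keep("20230401", NA))
})

test_that("cohort assembly partitions retained statin cases exhaustively", {
  tables <- mk_tables(
    demo = c("1$100$20200101$20200301",        # statin DILI
             "2$200$20200101$20200301",        # statin non-DILI
             "3$300$20200101$20200201",        # statin, temporally excluded
             "4$400$20200101$20200301",        # background case, DILI
             "5$500$20200101$",                # statin, no REAC rows
             "6$600$20210101$20210301",        # duplicate pair: v2 survives
             "7$600$20210301$20210301"),
    drug = c("1$1$PS$LIPITOR", "2$1$PS$ZOCOR", "3$1$PS$CRESTOR",
             "4$1$PS$METFORMIN", "5$1$PS$LIPITOR", "6$1$PS$LIPITOR",
             "7$1$PS$LIPITOR"),
    reac = c("1$Hepatitis", "2$Nausea", "3$Liver injury", "4$Hepatitis",
             "6$Hepatitis", "7$Nausea"),
    ther = c("1$1$20200201", "3$1$20200215")   # case 3: start after event
  )
  co <- assemble_cohort(tables, test_dict, test_smq)
  # dedup: 6 cases; case 300 excluded; 5 retained
  expect_equal(co$report$dedup$n_cases, 6)
  expect_equal(co$report$n_excluded_temporal, 1)
  expect_equal(co$excluded$caseid, "300")
  expect_equal(co$report$n_retained, 5)
  # partition over retained statin cases: DILI + non-DILI
  statin <- co$cases[co$cases$has_statin, ]
  expect_equal(nrow(statin), 4)
  expect_setequal(statin$caseid[statin$is_dili], c("100"))
  # case with no REAC rows is non-DILI
  expect_false(co$cases$is_dili[co$cases$caseid == "500"])
  # background case stays in the universe but not in the statin set
  expect_true("400" %in% co$cases$caseid)
  expect_false(co$cases$has_statin[co$cases$caseid == "400"])
  # duplicate resolved to the later receipt (primaryid 7, non-DILI version)
  expect_false(co$cases$is_dili[co$cases$caseid == "600"])
  # conservation: retained + excluded = deduplicated cases
  expect_equal(co$report$n_retained + co$report$n_excluded_temporal,
               co$report$dedup$n_cases)
})

test_that("therapy start prefers the statin-linked row with case fallback", {
  tables <- mk_tables(
    demo = c("1$100$20200101$20200610", "2$200$20200101$20200610"),
    drug = c("1$1$C$ASPIRIN", "1$2$PS$LIPITOR",
             "2$1$PS$LIPITOR"),
    reac = c("1$Hepatitis", "2$Hepatitis"),
    ther = c("1$1$20200101",   # aspirin start (earlier, unlinked)
             "1$2$20200301",   # statin start: the linked one wins
             "2$3$20200401")   # no row matches drug_seq 1: fallback
  )
  co <- assemble_cohort(tables, test_dict, test_smq)
  expect_equal(co$cases$start_dt[co$cases$caseid == "100"], "20200301")
  expect_equal(co$cases$start_dt[co$cases$caseid == "200"], "20200401")
  expect_equal(co$cases$onset_days[co$cases$caseid == "100"], 101L)
})

test_that("reassembling the cohort from its own universe is a no-op", {
  cfg <- synthetic_config(seed = 5, n_cases = 400)
  db <- generate_faers(cfg)
  tabs <- list(demo = read_faers_table(faers_lines(db$demo), "DEMO")$records,
               drug = read_faers_table(faers_lines(db$drug), "DRUG")$records,
               reac = read_faers_table(faers_lines(db$reac), "REAC")$records,
               outc = read_faers_table(faers_lines(db$outc), "OUTC")$records,
               ther = read_faers_table(faers_lines(db$ther), "THER")$records)
  co1 <- assemble_cohort(tabs, test_dict, test_smq)
  tabs2 <- tabs
  tabs2$demo <- tabs$demo[tabs$demo$primaryid %in% co1$cases$primaryid, ]
  co2 <- assemble_cohort(tabs2, test_dict, test_smq)
  expect_equal(sort(co2$cases$primaryid), sort(co1$cases$primaryid))
  expect_equal(co2$report$n_statin_dili, co1$report$n_statin_dili)
})
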