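# statindili

Pharmacovigilance signal detection for statin-associated drug-induced liver
injury (DILI) in FAERS-style spontaneous-report databases.

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) are the main post-marketing window onto rare drug harms, but turning
their quarterly `$`-delimited tables into defensible signal statistics takes
a chain of easily-botched steps: report-version deduplication, free-text
drug-name standardisation, event definition through a MedDRA query, temporal
plausibility filtering, and disproportionality estimation against the right
comparator. `statindili` implements that chain end-to-end for the eight
statins (atorvastatin, cerivastatin, fluvastatin, lovastatin, pitavastatin,
pravastatin, rosuvastatin, simvastatin) and hepatic injury defined by the
narrow scope of the hepatic-disorders SMQ, and ships a synthetic five-table
database generator with planted truth so every stage is testable without
downloading anything.

It is intended for pharmacoepidemiologists and biostatisticians who want a
reproducible, scriptable alternative to spreadsheet-and-SQL workflows for
this class of analysis.

## The statistics

For each target drug, cases are cross-classified against all other reports
in the loaded universe:

|              | DILI | non-DILI |
|--------------|------|----------|
| target drug  | a    | b        |
| other reports| c    | d        |

Two disproportionality measures are computed:

* **Reporting odds ratio** — ROR = (a/b)/(c/d), with the Woolf 95% CI
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)), no continuity correction.
* **Information component** — IC = log₂(a·N / ((a+b)(a+c))), the
  observed-over-expected log ratio in bits, with either the Norén
  asymmetric approximation or a gamma-posterior quantile interval
  (both shipped as approximations; configurable).

A drug is a **signal** only when both rules fire: a ≥ 3 and ROR CI lower
limit > 1; and IC > 1 with credibility lower bound > 0.

Around the estimators sit the cohort rules: one record per `CASEID`
(latest `FDA_DT`, ties to the higher `PRIMARYID`), primary-suspect (PS)
exposures only, dictionary-based name standardisation, one DILI record per
case however many SMQ terms matched, and exclusion of cases whose therapy
start is strictly later than the event date.

## Worked example

Generate a 20,000-case synthetic database whose composition mirrors the
published statin-DILI study (drug shares, planted RORs, outcome and onset
distributions), run the pipeline, and look at the signals:

```r
library(statindili)
res <- run_pipeline(run_config(
  synthetic = synthetic_config(seed = 42, n_cases = 20000),
  seed = 42))
res$signals[, c("drug", "a", "b", "ror", "ror_l", "ic", "ic_l", "signal")]
```

```
# A tibble: 8 × 8
  drug             a     b   ror  ror_l      ic   ic_l signal
  <chr>        <int> <int> <dbl>  <dbl>   <dbl>  <dbl> <lgl>
1 atorvastatin    92  1853  2.28  1.81   0.988   0.643 FALSE
2 cerivastatin     0     1 NA    NA     NA      NA     FALSE
3 fluvastatin      7    30  9.68  4.23   2.99    1.69  TRUE
4 lovastatin       2    43  1.91  0.461  0.898  -1.70  FALSE
5 pitavastatin     0    35 NA    NA     NA      NA     FALSE
6 pravastatin      4   160  1.02  0.378  0.0323 -1.73  FALSE
7 rosuvastatin    42   976  1.83  1.33   0.791   0.277 FALSE
8 simvastatin     47   676  3.05  2.23   1.45    0.962 TRUE
```

Reading the fluvastatin row: 7 DILI and 30 non-DILI reports give an
estimated ROR of 9.7 (planted value 6.9) with a CI entirely above 1, and an
IC of 3.0 bits with a positive lower bound — both rules fire, so it is
flagged. At this reduced scale the small statins carry only a handful of
cases, so several planted associations are not yet detectable (cerivastatin
and pitavastatin have no DILI case at all and their estimates are reported
as undefined rather than patched) — exactly the minimum-case behaviour the
dual criteria are designed to enforce. The atorvastatin IC point estimate
lands just under the 1-bit threshold here, so it is not flagged despite an
elevated ROR; at the full published scale its IC is 1.56 and it is.

`res$demographics`, `res$onset`, `res$annual_counts` and `res$dose_trend`
hold the descriptive rollups; `res$attrition` records the case counts at
every stage boundary. With `out_dir` set, everything is written as CSV plus
a `run_metadata.json`, byte-identical across reruns of the same seed.

A thin command-line wrapper ships at `inst/cli/pv.R`
(`Rscript pv.R run -c config.yaml`; see `inst/extdata/example_config.yaml`).

## Layout

* `R/` — ingestion (`read_faers_table`), dedup (`dedupe_cases`), drug
  mapping (`normalize_drug_name`), cohort (`assemble_cohort`), signals
  (`signal_table`, `ror_estimate`, `ic_estimate`), descriptives, the
  synthetic generator (`generate_faers`) and the pipeline (`run_pipeline`).
* `inst/extdata/` — drug dictionary, country→region table, synthetic SMQ
  term list (a labelled stand-in; MedDRA licensees should substitute the
  official narrow-scope export), printed-value fixture, example config.
* `vignettes/statin-dili-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design and limitations.
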