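---
title: "Methods: disproportionality analysis of statin-associated DILI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of statin-associated DILI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statindili)
options(statindili.quiet = TRUE)
```

## The problem and the data model

Spontaneous-report databases collect unverified adverse-event reports.
Each *case* may be submitted several times (report versions sharing a
`CASEID` under distinct `PRIMARYID`s), names drugs as free text, codes
reactions as MedDRA Preferred Terms (PTs), and records dates at whatever
precision the reporter supplied (year, month, or day). `statindili` turns
the five quarterly tables (DEMO, DRUG, REAC, OUTC, THER) into one analysed
case per `CASEID` and asks, for each of the eight statin generics, whether
hepatic-injury reports are disproportionally frequent relative to the rest
of the database.

The cohort rules, in pipeline order:

1. **Deduplication.** Per `CASEID`, keep the report with the latest
   `FDA_DT`; ties go to the numerically higher `PRIMARYID`. Child-table
   rows of superseded versions are dropped in the same pass.
2. **Exposure.** Drug names are standardised by exact dictionary lookup
   (after uppercasing, whitespace collapsing and salt-suffix stripping);
   only *primary suspected* (PS) roles count as exposure.
3. **Event.** A case is DILI iff at least one of its PTs belongs to the
   narrow scope of the hepatic-disorders SMQ; multiple matching PTs still
   contribute a single DILI record.
4. **Temporal plausibility.** Cases whose therapy start is *strictly*
   later than the event date (compared at the coarsest common date
   precision) are excluded — they describe liver injury that predates the
   drug.

## Estimators

With cells $a,b$ (target drug, DILI / non-DILI) and $c,d$ (all other
reports), the reporting odds ratio is
$\mathrm{ROR} = (a/b)/(c/d)$ with the Woolf interval
$\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$,
and the information component is
$\mathrm{IC} = \log_2 \frac{aN}{(a+b)(a+c)}$ (bits), the observed count
over its expectation under independence. A drug is flagged only when both
rules fire: $a \ge 3$ and ROR lower limit $> 1$; IC $> 1$ and credibility
lower bound $> 0$. The conjunction trades sensitivity for a lower
false-positive rate, the usual posture in hypothesis-generating
pharmacovigilance.

**Assumptions worth stating.** Disproportionality is not incidence: both
measures compare reporting odds inside a reporting system shaped by
prescription volume, publicity and secular trends. The comparator is "all
other reports in the loaded universe" — with a full database the baseline
is the database-wide DILI reporting odds (about 0.017 in the published
setting this package reproduces). When only a statin extract is loaded the
tool warns, because the comparator is then other statins and estimates
shrink toward 1.

## Numerical and design choices

* **IC without shrinkage.** The point estimate is the unshrunk
  $\log_2(a/E)$; this is the only form consistent with every published
  per-drug IC value we validate against (e.g. an IC of 3.46 at $a=6$
  requires $\log_2(6/E)$, not $\log_2(6.5/(E+0.5))$). The BCPNN-style
  $+0.5$ stabilisation is available behind `shrinkage = TRUE`.
* **IC intervals are approximations.** Two methods ship: the Norén
  asymmetric formula (default) and gamma-posterior quantiles. Neither
  reproduces the published credibility bounds exactly (the published
  cerivastatin lower bound of −0.54 is wider than either approximation
  gives), so the decision-rule validation feeds the *published* bounds
  rather than recomputed ones, and both methods are labelled
  approximations in the output.
* **Zero cells are undefined, not patched.** Any zero cell yields `NA`
  estimates; the $a \ge 3$ gate then fails the drug. A Haldane $+0.5$
  flag exists for exploratory use only.
* **Partial dates.** All date logic runs on canonical 4/6/8-digit strings.
  Comparisons truncate to the coarsest common precision; a strict
  inequality at that precision is required to call one date "later". This
  makes the temporal exclusion conservative: missing or coarse dates never
  exclude a case. Receipt-date ties created by coarsening are resolved by
  the `PRIMARYID` rule and counted in the dedup report.
* **Onset.** Time to onset = event date − earliest therapy start, defined
  only when both dates have day precision and the difference is
  nonnegative. Start dates are linked to the statin's `drug_seq` via THER
  `dsg_drug_seq`, falling back to the case-level earliest start when
  linkage is absent. Quartiles use the linear-interpolation convention
  (`quantile type 7`); published interquartile ranges cannot disambiguate
  the convention, so it is fixed and documented. Onset groups are compared
  by one-way ANOVA with uncorrected pairwise Welch tests — mirroring how
  such comparisons are conventionally reported — with a Kruskal–Wallis
  p-value alongside, since latencies are heavily right-skewed and the
  rank-based test is the more defensible choice.
* **Percentages** are rounded half-up at two decimals, matching how
  published tables print proportions (base `round()` is banker's
  rounding and would disagree at `.005` boundaries).
* **Multi-statin cases.** A report with two PS statins counts once per
  statin in per-drug tables and once overall; the published analysis does
  not state its handling, so this choice is documented rather than
  inferred.
* **Chi-square tests** (`stats::chisq.test`, no continuity correction)
  refuse tables with an all-zero margin by naming the offending row or
  column; silent collapsing would change the degrees of freedom.

## The synthetic generator

`generate_faers()` emits the five tables plus an exact truth ledger. Its
defaults *are* the published study's conditions: per-drug shares
proportional to the published report totals, planted RORs equal to the
published estimates, a background DILI proportion of 0.01695 (the value
the published table jointly implies), outcome mixes from the published
outcome distribution, and log-normal onset latencies centred on the
published per-drug medians with $\sigma = 1.5$ (chosen once from the
spread of the published interquartile ranges). Dates are emitted at day
precision and degraded (45% of event/start dates absent or coarsened, so
that roughly the published fraction of DILI cases retains computable
onsets). Statins occupy 20% of the generated database: the real-world
fraction (~1%) would leave the rare statins without a single expected
case at desk scale, and 20% keeps every pipeline branch exercised while
the background bucket still dominates the comparator. Duplicate report
versions (10% by default) are constructed so the intended survivor is
known — later receipt date *and* higher `PRIMARYID` — and a hostile mode
emits receipt-date ties so only the tie-break identifies the survivor.

One consequence of planting odds per drug: the planted ROR is defined
against the *pure background* odds, while the pipeline estimates against
"all other reports", which includes the other DILI-enriched statins. At
the default composition this attenuates estimates by roughly 10–15% for
the large statins. Recovery properties are therefore tested on
single-target configurations (one statin plus background), where the two
definitions coincide; ranking and ledger properties use the full default
mix. The truth ledger's cells are *realised* counts, so ledger equality is
exact regardless of composition.

What the generator does **not** emulate: reporting biases (Weber effect,
stimulated reporting), drug–drug interaction structure, within-case
correlation between demographics and exposure, indication channeling, or
free-text noise beyond brand/salt variants present in the dictionary.
Passing tests therefore demonstrate that the *machinery* is correct under
the planted model, not that real-extract estimates are unbiased.

## Validation strategy and problem sizes

Three layers, all in `tests/testthat/`:

* **Printed-value cross-consistency.** The published per-drug table omits
  the comparator cells, but all drugs share one comparator, so its odds
  $q = c/d$ are identifiable: `recover_background()` fits $q$ by least
  squares on relative error (closed form, quadratic in $1/q$) over the
  four largest drugs, and the held-out drugs' ROR, CI bounds and IC are
  re-derived and compared at 1% / 0.02-bit tolerances. A numeric 1-D
  minimiser serves as the independent oracle for the fit itself.
* **Planted-truth recovery.** Ledger equality of contingency cells under
  20% duplicates and brand variants (exact, n = 3,000); hostile-tie dedup
  (n = 1,500); Woolf-interval coverage between 93% and 97% over 500
  binomial replicates at planted ROR 2 and expected $a \approx 100$;
  onset-median recovery within 10% at ~560 planted samples; closed-form
  agreement with a brute-force oracle to $10^{-12}$ on 1,000 random
  tables.
* **Desk-scale study run.** The default configuration at n = 50,000 runs
  end-to-end and must rank atorvastatin first by DILI share and
  fluvastatin first by ROR among evaluable targets ($a \ge 3$), the
  qualitative fingerprint of the published analysis.

Sizes were chosen so the whole suite runs in about a minute on one core
while keeping every stochastic assertion at ≥ 3 standard errors of
headroom; they are package choices, not statements about the limits of
the method.

## Known limitations

* The shipped SMQ term list is a synthetic stand-in (MedDRA is licensed);
  with it, absolute DILI classifications on *real* extracts will differ
  from analyses using the official 144-term narrow list. The file format
  makes substitution trivial, and all internal validation is term-list
  agnostic.
* The dictionary mapper is exact-match by design; free-text forms like
  `"LIPITOR 20MG TAB"` stay unmapped unless added to the CSV. No fuzzy
  matching, by policy — silent mis-mapping is worse than a counted
  unmapped name.
* `EVENT_DT` is taken from DEMO, and therapy linkage falls back to the
  case level when `dsg_drug_seq` does not match; both are stated
  conventions where real extracts are ambiguous.
* No multiplicity correction across drugs, no PRR/EBGM estimators, and no
  causality adjudication: the output is a screening signal, not an
  incidence or risk estimate.
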