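---
title: "Disproportionality signal detection: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

faersignal implements a complete case–noncase analysis pipeline for
spontaneous adverse-event reports in the FAERS ASCII dialect, aimed at
comparing the reporting profiles of the four dihydropyridine calcium
channel blockers (DHP-CCBs) amlodipine, felodipine, nicardipine and
nifedipine. This vignette documents the statistical model, every tunable
parameter that matters, the synthetic-data generator used for
validation, and the numerical choices made where conventions diverge.

## The counting model

All statistics are computed on 2×2 contingency tables. The analysis
unit is one **distinct (report, preferred term) pair**, with drug
exposure defined at report level:

|                  | event PT | other PTs |
|------------------|----------|-----------|
| report carries drug     | a | b |
| report without drug     | c | d |

Pair-level counting (rather than report-level) is the only counting
unit consistent with published FAERS top-20 tables in which a single
drug's twenty PT counts can exceed its report total; it also yields a
stable universe size N across rows of such tables. Duplicate mentions
of the same PT within one report collapse to a single pair.

Two backgrounds are supported. Under the *full* background the pair
universe is every cleaned report. Under the *class* background it is
restricted to reports carrying any DHP-CCB (ATC C08CA) ingredient, and
"without drug" means class reports not carrying the target — reports
carrying the target plus another class drug stay on the exposed side,
so the two columns partition the universe.

## The four statistics and the consensus rule

With `z = 1.96` throughout:

* **ROR** (reporting odds ratio): `ad/bc`, Woolf limits
  `exp(log ROR ± z sqrt(1/a + 1/b + 1/c + 1/d))`. Signal: `a ≥ 3` and
  lower limit `> 1`.
* **PRR** (proportional reporting ratio): `[a/(a+b)]/[c/(c+d)]`, limits
  `exp(log PRR ± z sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`. Signal:
  `a ≥ 3` and lower limit `> 1`.
* **MHRA rule**: Yates-corrected chi-square
  `N(|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))`, truncated to zero
  when `|ad − bc| ≤ N/2`. Signal: `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`.
* **BCPNN information component**: `E = (a+b)(a+c)/N`,
  `IC = log2((a + 0.5)/(E + 0.5))`, and the closed-form credibility
  approximation `IC025 = IC − 3.3 (a + 0.5)^−1/2 − 2 (a + 0.5)^−3/2`.
  Signal: `a ≥ 3` and `IC025 > 0`.

A **consensus** signal requires all four simultaneously; the
conjunction is the pipeline's only false-positive control (no
multiplicity correction is applied, deliberately mirroring standard
pharmacovigilance practice).

Numerical choices worth knowing:

* **Zero cells.** If any cell is zero, 0.5 is added to all four cells
  (Haldane–Anscombe) before ROR/PRR/χ² computation. Signal flags always
  use the raw `a`, so the correction can never create a signal at
  `a < 3`. The IC shrinkage form needs no correction.
* **Yates vs plain χ².** The continuity-corrected form is used because
  it reproduces published MHRA tuples to within 0.02% through the
  inversion oracle, where the uncorrected statistic misses by ~0.5%.
* **z = 1.96**, not 1.959964: matches intervals printed at two decimals.

## The inversion oracle

Published signal tables print, per row, the count `a`, the ROR point,
the PRR point and the PRR lower limit — but not the 2×2 table. These
four numbers over-determine the table, so it can be recovered in closed
form. Writing `R` and `P` for the ROR and PRR points, `L` for the PRR
lower limit and `w = c/(c+d)`:

```
w = (R − P) / (P (R − 1))      u = a + b = a / (P w)
V = (log(P / L) / z)^2         c = (1 − w) / (V − 1/a + 1/u)
d = c (1 − w) / w              b = u − a
```

`invert_stats()` implements this; recomputing the forward statistics
from the reconstructed cells reproduces every *other* printed column
(the unused ROR limits, χ², IC025) to within two-decimal rounding of
the inputs. This is the package's validation route against published
results: it needs no access to the source database, and agreement on
quantities *not* used by the inversion is strong evidence that the
forward formulas match those behind the publication. The test suite
checks nine published rows this way (tolerance 0.5% relative for ROR
limits and χ²; ±0.03 absolute for IC025, absorbing the two-decimal
rounding of the inputs).

## Cleaning rules

* **Deduplication**: one report version per `caseid` — the most recent
  `fda_dt`, ties broken by the largest `primaryid`. Rows missing
  `caseid`, `primaryid` or `fda_dt` are dropped; missing sex or age are
  *not* grounds for exclusion (they become "unknown" categories).
* **Reporter filter**: occupations MD (physician), PH (pharmacist), HP
  (other health professional) retained; consumer, lawyer and unknown
  reports dropped.
* **Role filter**: drug mentions qualify with roles PS, SS or I;
  concomitant (C) mentions are ignored, and a report left with no
  qualifying mention is dropped.
* **Drug resolution**: uppercase, trimmed matching of `prod_ai` and
  `drugname` against a synonym dictionary, splitting combination
  products on `\`, `+`, `;`, `/` and stripping salt/ester suffixes
  (besylate, maleate, ...; configurable via
  `options(faersignal.salt_suffixes=)`). No fuzzy matching.
* **Age**: units DEC/YR/MON/WK/DY/HR normalised to years; a present age
  with a missing unit is taken as years with a warning. This fallback
  is a documented convention choice, not something the reporting form
  guarantees. Age bins: [0,18), [18,44], (44,64], (64,75], (75,∞).

## Case–noncase logistic regression

For suicide-related outcomes the pipeline fits
`outcome ~ drug + sex + age_group + occupation` by maximum likelihood
(IRLS via `glm`), outcome 1 when the report's PT set contains the
outcome term. Reference levels: amlodipine, male, 18–44, physician.
Reports carrying two or more target drugs are excluded rather than
multiply counted — the paper-level unit keeps within-case correlation
out of the likelihood — and reports with unknown sex/age are excluded
and counted, not imputed. Wald intervals and p-values are reported
(the conventional aOR / 95% CI / p triplet); with a single binary
predictor the fitted aOR equals the 2×2 odds ratio exactly, which the
tests assert to 1e-8.

## Sensitivity analyses

Three composable, idempotent, mutually commuting report-level filters:

* `exclude_comedication()`: drop reports co-mentioning (any role) any
  ingredient on a list; the default list covers common antidepressants
  (ATC N06A) and antipsychotics (N05A). Probes confounding of
  suicide-related signals.
* `exclude_pregnancy_indications()`: keep reports that either carry no
  target drug (they remain background) or carry it as primary suspect;
  drop reports whose indications include pregnancy-related conditions
  (gestational hypertension, pre-eclampsia, eclampsia, tocolysis-type
  indications). PS status is evaluated for the *target* drug — the
  reading adopted where the convention is ambiguous — because the bias
  this filter probes is indication-driven prescribing of the target.
* `stratify_physician()`: physician-submitted reports only.

Signal detection is re-run on the filtered cohort with fully recomputed
margins (the universe shrinks; the primary run's margins are never
reused), and `compare_runs()` reports per-pair persistence with the
first failing criterion when a signal is lost.

## The synthetic-data generator

`generate_reports()` draws FAERS-dialect bundles from a fully specified
generative model so every pipeline stage can be validated against known
ground truth:

* **Exposure**: independent Bernoulli per drug; a case that draws no
  drug is assigned one (proportionally to exposure probabilities), as a
  FAERS report must name a drug. One exposed drug, chosen at random,
  is the primary suspect; the rest are SS or I.
* **PT sets**: the number of PTs per report is
  `1 + Poisson(pts_per_report_mean − 1)` (truncated at the catalog
  size), guaranteeing at least one reaction. PTs are drawn from the
  baseline multinomial re-weighted by the planted multipliers of the
  report's drugs and renormalised; repeated draws collapse to distinct
  pairs.
* **Duplicates**: with probability `dup_prob` a case emits one
  follow-up version with a strictly later `fda_dt`, a larger
  `primaryid`, and possibly one mutated field — exercising the
  "most recent wins" deduplication semantics.
* **Demographics, outcomes, indications**: categorical draws with
  configurable missingness; dates are yyyymmdd integers in the
  2014Q3–2024Q4 study window.

`expected_cells()` returns the analytic first-order expectations of the
2×2 cells under this model (exact in the rare-PT limit). Two
deliberate approximations: the per-report PT-set deduplication is
ignored (it tilts rare-PT pair shares up by a few percent, equally on
the exposed and background sides, so ratios are unaffected), and the
planted multiplier's renormalisation means the realised rate ratio for
a planted pair is `r / (1 + p (r − 1))` with baseline probability `p`
— for `r = 8` at `p = 0.002`, about 7.89 rather than 8.

Default generator conditions (chosen once, as plausible for a
spontaneous-reporting system, and not tuned): 55% female, physicians
the largest reporter group with ~70% of reports from the retained
occupations, 20% follow-up rate, mean two PTs per report, mostly
year-coded ages with occasional month/decade/day units, and a drug
catalog in which amlodipine has the largest exposure among the targets.

**What passing tests do and do not show.** The generator emulates the
structural features the pipeline's logic depends on (roles,
occupations, duplicates, multi-PT reports, planted disproportionality);
it does not emulate reporting dynamics over time, country-specific
behaviour, name misspellings, or correlated drug co-prescription.
Recovery of a planted multiplier therefore validates the pipeline's
arithmetic and plumbing, not the epidemiological interpretability of
signals on real data.

## Validation problem sizes

The shipped suite exercises, among others: nine published-row
reproductions through the inversion oracle; an exhaustive sweep of all
2×2 tables with cells ≤ 25 against independently coded formulas; 1,000
random-table inversion round-trips; 100 seeded end-to-end recovery runs
at 200,000 cases with an eightfold multiplier planted on a
0.002-baseline PT (consensus detection and ROR-CI coverage each
required in ≥ 90 runs); 20 seeded null runs at 20,000 cases (consensus
false-flag rate ≤ 2% of eligible pairs); and 100 seeded logistic
coverage runs at 50,000 rows with a true twofold drug effect (Wald CI
coverage within [91%, 99%]). These sizes were chosen to keep each
property informative while the whole suite remains comfortably
runnable on a laptop.

## Known limitations

* The '$'-delimited dialect has no quoting; an embedded '$' in a value
  cannot be represented.
* PT strings are opaque labels: no MedDRA hierarchy ships with the
  package, so SOC-level aggregation is out of scope.
* The full Monte-Carlo BCPNN posterior is not implemented; the
  closed-form IC025 approximation is the default and matches published
  values to ±0.01 in the rows checked.
* No Firth correction: complete separation in the regression surfaces
  as a convergence error rather than a penalised fit.
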