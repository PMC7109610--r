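---
title: "Costing and validating health resource utilization surveys with mshrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing and validating health resource utilization surveys with mshrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshrs)
```

## The problem

Cost-of-illness work in multiple sclerosis (MS) needs patient-level resource
use measured across the whole societal perspective: hospital and
rehabilitation stays, ambulant consultations, examinations, out-of-pocket
spending, professional and informal care, and productivity losses from
absenteeism, presenteeism and disability pension. `mshrs` implements a
complete costing and validation pipeline for a 24-item health resource
utilization survey of this kind: it scores per-respondent answers into
monetized quarterly cost breakdowns by microcosting (every consumed unit is
priced individually), and it implements the psychometric machinery used to
validate such an instrument — test-retest reliability in a stable subgroup,
Guttman lower-bound consistency coefficients, convergent/discriminant
correlations, and known-group analyses across disability strata.

Because the original study data are not public, the package also ships a
first-class synthetic cohort generator. Every analysis stage can therefore
be exercised end to end, and the statistical estimators can be checked by
parameter recovery against known generating values.

## The costing model

Each respondent-wave record is priced per quarter:

* **Count items** (inpatient days, day admissions, consultations,
  examinations) are recall-scaled to the quarter,
  `q * quarter_days / recall_days` with `quarter_days = 91.25` (365/4), and
  priced at per-unit costs. Recall windows above 365 days are rejected on
  load: long windows produce telescoping, and the instrument's convention is
  that recall never exceeds 12 months.
* **Weekly-rate items** (professional and informal care hours, working
  hours) use 13 whole weeks per quarter. Informal care is valued at
  opportunity cost with a 60 h/week cap; hours beyond the cap are recorded
  but not priced.
* **Out-of-pocket expenditures** (over-the-counter medication, consumables,
  investments net of grants) pass through as reported and are indexated to
  the valuation's reference year at the configured inflation rate (2%/year
  by default). Grants are netted before indexation.
* **Productivity losses** follow the human capital approach. One sick day
  costs `annual_work_hours / annual_work_days * hourly_labor_cost`
  (1406.2 / 233 x EUR 29.90 ~ EUR 180.45 under the default 2011 German
  tables). Disability pension is the percentage share of the annual
  full-disability value, capped at EUR 42,045.38 (= 1406.2 x 29.90) and
  spread evenly over quarters. Presenteeism maps the 0-10 Likert answer
  linearly to a lost-productivity fraction (`score/10`) applied to hours
  actually attended — contracted hours net of sick days at
  `weekly_hours / 5` contracted hours per sick day — so that presenteeism
  never double-counts absenteeism. The linear Likert mapping and the
  attended-hours base are the minimal assumptions consistent with "any hour
  not worked is lost"; the multiplication principle itself does not fix a
  base.
* **Disease-modifying therapies** (DMTs) are priced annually per drug-year
  (defined daily dose net costs x 365); the quarterly share is annual/4.
  By reporting convention DMT costs are excluded from the "direct medical"
  subtotal and carried separately; totals are reported with and without
  them. Assessment years outside the price table's 2010-2017 coverage are
  served by indexation from the nearest covered year.

All monetary constants live in a versioned YAML config
(`inst/extdata/valuation_de2011.yaml`), not in code, because unit costs must
be updated and localized; the 2011 German tables ship as the default. A
config is validated on load: the pension cap must equal
`annual_work_hours x hourly_labor_cost` within half a cent and all unit
costs must be positive. Internal arithmetic is unrounded; cents appear only
in written outputs.

Missingness follows a strict no-imputation rule. An unanswered item is `NA`
(CSV empty cell, JSON absent key) and is never a zero; an explicit 0 is a
true zero, e.g. a gated follow-up item whose gate was answered "no".
Missing items propagate to missing components; subtotals are computed over
observed components only, with a per-row `complete` flag.

Two quantification choices deserve note. The instrument's stay items could
be collected as stays or as days; the schema stores *days* per ward type
because valuation is per day. Sick time is recorded in days only (not
hours), matching the instrument's usability decision. The quarterly
convention (91.25 days / 13 weeks) is a package choice — "per quarter" does
not itself define day and week counts — and both are configurable via
`period_model()`. Annualization is a flat x4; published annual means of the
original study were computed per patient over varying denominators and are
therefore not exactly 4x the quarterly means.

## The validation procedure

* **Stable subgroup**: test-retest reliability is estimated only in
  patients with no relapse and no EDSS increase during the retest period
  and the 3 months before baseline. The pre-window EDSS is an explicit
  field (`edss_pre`); records with missing history are excluded with a
  logged reason, not errors.
* **ICC(1,1)**: one-way random-effects intraclass correlation for single
  measurements, `(MSB - MSW) / (MSB + MSW)` for two measurements per
  subject, with bands poor/moderate/good/excellent at 0.5/0.75/0.9. Zero
  total variance is signalled as an explicit "undefined" condition.
* **Guttman lambda-2 / lambda-6**: lower-bound reliability coefficients
  computed over the monetized, standardized component costs excluding DMT.
  Items are standardized on the final quarterly monetized scale (after
  recall scaling); a zero-variance item or singular covariance is a named
  error, not a silent drop.
* **Known groups**: quarterly totals (excluding DMT) are compared across
  the EDSS strata 0-1.0, 1.5-2.5, 3.0-4.0, 4.5-5.5 with a Kruskal-Wallis
  omnibus test and all six pairwise Mann-Whitney tests under Bonferroni
  correction (`p_adj = min(1, 6 p)`; each outcome is its own family).
  Respondents outside every stratum (EDSS above 5.5) are excluded and
  counted. Rank statistics use midranks with tie-corrected variance; for
  tiny samples an exhaustive permutation mode (`exact = TRUE`) enumerates
  the full conditional distribution.
* **Convergent/discriminant validity**: Spearman rank correlations of
  totals with PRO summary scores, pairwise-complete. The package consumes
  PRO summary scores as numeric columns; it does not score EQ-5D, UKNDS,
  PRIMUS or TSQM instruments.

## What the synthetic cohort emulates — and what it does not

A single latent severity scalar per subject drives everything: the EDSS
stratum (by latent quantile), the occurrence probability and location of
every cost component, and the PRO scores. Components are zero-inflated
log-normal — many items have median 0 with a heavy right tail, the shape a
two-part model reproduces most simply. Default stratum probabilities,
employment, relapse distribution, DMT mix and completion rate follow the
published cohort's marginals; per-stratum component parameters were
calibrated once (at n = 30,000) so that mean quarterly totals rise
~1100/2300/2900/4600 across the four strata, matching the published
gradient's shape.

The **retest model** is a measurement model: each subject's latent
total-cost value is the normal-scores transform of their priced quarterly
total rescaled to `between_sd`, and both wave measurements add independent
Gaussian noise with `within_sd`, so the population ICC equals
`between_sd^2 / (between_sd^2 + within_sd^2)` exactly (defaults 1100/500,
implying 0.829). Measurements are deliberately not truncated at zero: they
are noisy readings of the latent value, and truncation would distort the
variance-components structure that makes honest parameter recovery possible.
A configurable fraction of subjects receives relapses or EDSS increases so
stable-subgroup filtering has both outcomes (defaults give ~50% stable).

**PRO scores** come from a Gaussian copula on the normal scores of total
cost: for a target Spearman correlation `r`, the Gaussian mixing weight is
`2 sin(pi r / 6)`. Ties among zero-cost respondents attenuate realized
correlations slightly; at the default calibration the realized values sit
within sampling tolerance of the targets at n = 2,000.

Passing tests on this cohort demonstrate that the estimators and the
pipeline are correct, not that real survey data behave this way. In
particular the synthetic components are conditionally independent given
severity, so consistency coefficients (lambda-2/lambda-6) of synthetic
cohorts are much lower than an instrument with correlated real-world
resource use would show; published cohort-level values (ICC 0.828 on real
stable patients, lambda-2 ~ 0.68) require the study data and are not
reproduction targets here. The generator also does not model longitudinal
disease progression beyond two waves, event-related relapse costing, or
treatment effects.

## Numerical choices and degenerate inputs

* Exact rational arithmetic for shares (completion rate) before display
  rounding; money rounded to cents only at file boundaries.
* ICC is clamped above by 1; `ms_between + ms_within = 0` raises a classed
  "undefined" condition which the report assembler converts to a
  `"reliability undefined"` status rather than an error.
* Permutation tests treat statistics within `1e-12` of the observed value
  as ties in its favor, the conservative convention.
* Empty strata, constant correlation vectors, single-item matrices, empty
  respondent groups and header-only input files all have defined behavior
  (classed errors, warnings, or flagged `NA`), exercised in the test suite.
* Problem sizes used by the shipped checks: oracle pricing equivalence at
  n = 1,000; ICC parameter recovery with 100 replicates at n = 1,000 per
  target ICC in {0.5, 0.83, 0.95} (within +-0.05 in at least 95% of
  replicates, the sampling-theory expectation at that n); known-group
  separation at ~500 per stratum; copula calibration at n = 2,000; and an
  end-to-end simulate/cost/validate run at n = 2,000.

## Worked example

```{r example, eval = FALSE}
library(mshrs)

spec <- cohort_spec(n = 500)
cohort <- generate_cohort(spec, seed = 42)
costs <- cost_responses(cohort, mshrs_valuation())
cohort_cost_summary(costs)

kg <- known_group_analysis(
  cost_responses(cohort, include_dmt = FALSE)$total_excl_dmt,
  cohort$edss)
glance(kg)
autoplot(kg)

retest <- generate_retest(cohort, spec)
reliability_report(retest, monetized_item_matrix(costs))
```

## Known limitations

* Price tables are 2011 German values; any other setting needs a localized
  config (the mechanism, not the data, is the deliverable).
* The x4 annualization convention differs from per-patient annualization
  over varying observation windows.
* Whether investments are netted of grants before or after indexation is a
  convention; the engine nets first, which is conservative when grants and
  prices inflate together.
* The exhaustive permutation mode is exponential and intended only for
  total n below about a dozen; larger samples use the standard asymptotic
  tie-corrected tests.
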