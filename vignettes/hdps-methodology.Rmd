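---
title: "High-dimensional propensity scores: model, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional propensity scores: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpstools)
```

## The estimation problem

In a cohort comparing initiators of one treatment with initiators of
another, the hazard ratio of an outcome is confounded by everything that
influences both treatment choice and outcome risk. Investigator-specified
covariates rarely exhaust this set: constructs such as frailty or disease
severity are not recorded directly, yet leave traces throughout a
patient's record — malnutrition diagnoses, repeated kidney-function tests,
particular prescription patterns. The high-dimensional propensity score
(HDPS) approach treats the code history itself as a reservoir of proxy
covariates, generates candidate indicators mechanically, ranks them by
their potential to confound, and adds the strongest to the propensity
score model.

This vignette documents the model and every place where the procedure
required a concrete numerical or design choice, followed by what the
synthetic validation does and does not establish.

## Pipeline and parameters

**Assessment windows.** Each code dimension carries a lookback window
ending at the patient's index date. The window is half-open,
`[index - L, index)`: a record dated exactly `L` days before entry counts,
a record on the index date does not, because baseline covariates must
precede treatment initiation. Typical settings, and the defaults of the
synthetic scenario, are the entire prior history for diagnoses, 90 days
for prescriptions, and 365 days for laboratory tests. Records for patients
absent from the cohort master are dropped with a logged tally — the cohort
master defines the population.

**Granularity.** Hierarchical codes are collapsed before counting:
truncation to a prefix (3 characters for ICD-9-like roots), an explicit
mapping table, or identity. Truncation length is a tunable with no
universal default; it trades resolution against sparsity.

**Candidate filter.** `identify_candidates()` defaults to the classical
`n = 200` most prevalent features per dimension with `min_patients = 10`,
but the pipeline defaults disable both (`n = Inf`, `min_patients = 1`):
prevalence filtering is a computational convenience whose value is
debated, and at the problem sizes this package targets it is unnecessary.
The "prevalence closest to 0.5" ordering used by some implementations is
deliberately not offered; ranking is by prevalence, descending, with ties
broken lexicographically by feature identifier so results are identical
across platforms and runs.

**Recurrence cutoffs.** For each feature the three candidate cutoffs are
1, the median, and the 75th percentile of occurrence counts *among
patients with at least one occurrence*. Computing quantiles over the full
cohort would usually give a median of zero and collapse all three
covariates into one; restricting to patients with the code follows the
original algorithm. Quantiles use the nearest-rank definition (the value
at order statistic `ceiling(p * m)`), so cutoffs are always attainable
integer counts. When cutoffs coincide the duplicate covariates are
dropped, keeping the earliest suffix in the order once → sporadic →
frequent: perfectly collinear columns destabilise the PS fit and waste
top-N budget.

**Zero-cell correction.** Both 2×2 tables (covariate × exposure,
covariate × outcome) are corrected independently: if any of a table's four
cells is zero, 0.1 is added to *all four cells of that table*; tables
without zeros are untouched, making the operation idempotent. This keeps
every risk ratio finite so that no covariate is silently excluded from
prioritisation.

**Bross score.** The bias multiplier uses the covariate prevalence in each
arm and the crude cohort-wide outcome risk ratio `RR_CD`. Two readings
required a decision. First, `RR_CD` is computed cohort-wide rather than
among the unexposed only (a known variant); cohort-wide is the simpler
reading and is applied uniformly. Second, when `RR_CD < 1` its reciprocal
enters the formula (on by default, switchable via `invert_protective`):
prioritisation targets the *magnitude* of potential confounding, and
without inversion protective covariates would be systematically
down-ranked. Ties in `|log bias|` are again broken lexicographically.

**Instrument-like flagging.** A covariate with `|log RR_CE| > 1.5` and
`|log RR_CD| < 0.5` (both strict) is flagged as empirically behaving like
an instrument; adjusting for such variables can amplify residual bias, so
sensitivity analyses may remove them (`remove_iv = TRUE`).

**Weights.** Stabilised weights are `p̄/ps` for the exposed and
`(1-p̄)/(1-ps)` for the unexposed. "Trimmed at the 99th percentile" is
implemented as *capping* at the percentile of the pooled (both-arm) weight
distribution, not as excluding patients: capping reduces the variance
contribution of extreme weights without changing the population the
estimand refers to. The percentile uses R's default linear-interpolation
quantile. Propensity scores numerically at 0 or 1 are clipped to
`[1e-6, 1 - 1e-6]` with a warning.

**Separation.** With hundreds of sparse binary covariates,
quasi-separation of the logistic PS model is a practical certainty at some
point. The fit falls back to a weak ridge penalty (`lambda = 1e-3`,
reported via a message) when the maximum-likelihood fit fails to converge,
sits on the boundary, or produces fitted probabilities numerically at 0 or
1 — the deviance can converge while coefficients diverge, so fitted-value
and coefficient-magnitude checks back up the convergence flag.

**Outcome model.** The weighted Cox model regresses the outcome on
exposure alone and uses a robust sandwich variance: weighting induces
dependence that the model-based variance understates. The 95% interval is
`exp(log HR ± 1.96 · SE)`.

**Balance.** The absolute standardised difference uses the pooled form —
for a binary covariate `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0))/2)`, with
weighted prevalences under a weighting scheme; the continuous analogue
substitutes means and variances. The conventional 0.10 threshold labels a
covariate well-balanced. Balance reports group covariates as predefined
versus proxy covariates above/below rank 150, a boundary at which balance
behaviour typically changes; it is configurable.

## The synthetic cohort generator

Because real hospital-authority data cannot be shipped, validation rests
on a generator that reproduces the *structure* the pipeline consumes: a
latent binary confounder `U` (prevalence 0.3) raises the exposure log-odds
by `alpha1 = 1.0` and the outcome log-hazard by `beta_u = 0.7`; thirty
proxy codes, spread across the three dimensions in proportion to their
size, have Poisson recording rates of 0.3 under `U = 0` and four times
that under `U = 1`, so presence and recurrence of these codes carry
information about `U`. Remaining codes are uninformative noise with rates
drawn from (0.05, 0.6). Age and sex act as measured confounders with
modest coefficients (0.3 per SD of age on both scales, −0.2 for female sex
on exposure). The exposure intercept (−0.7) puts exposure prevalence near
0.40, and an exponential outcome with baseline hazard 0.02/year censored
administratively at 10 years yields roughly a 20% event fraction — values
in the range of a large new-user antihypertensive cohort. Scenarios whose
realised exposure prevalence leaves (0.05, 0.95), or that produce no
events, are rejected with a diagnostic rather than silently analysed.

Record dates are drawn uniformly within each dimension's window (1 to `L`
days before index), so windowing logic sees date variation but no record
ever falls outside its window by construction; windowing correctness is
therefore tested separately with hand-built tables. Occurrence counts are
Poisson — the simplest count model that produces a meaningful median/75th
percentile recurrence structure.

What the generator does *not* emulate: code autocorrelation within
patients, calendar trends, informative censoring, measurement of exposure
duration or dose, and coding-system idiosyncrasies. Consequently, passing
the validation below demonstrates that the machinery is correct and that
proxy adjustment recovers a latent confounder *of the planted kind*; it
does not certify performance on any particular real database.

## Validation

The test suite validates each operation against independent oracles
(brute-force counting, direct arithmetic of the closed-form bias, order
statistics), and the end-to-end behaviour on the scenario above at
`n = 20 000` over 20 replicate seeds, a size chosen to keep Monte-Carlo
error well inside the decision margins while the whole suite runs in
minutes:

* under a null treatment effect, the crude estimate carries the planted
  bias (mean `|log HR|` ≈ 0.23) while the HDPS-adjusted estimate (top 50
  covariates) is close to null (≈ 0.03);
* a true hazard ratio of 0.8 is recovered by the adjusted estimate within
  [0.75, 0.85] on average;
* the number of imbalanced covariates (ASD ≥ 0.10) drops when the proxy
  covariates enter the weights;
* setting `n_select = 0` reproduces the predefined-only analysis
  bit-exactly, and unit weights reproduce the unweighted Cox fit
  bit-exactly.

`scripts/acceptance.R` re-runs exactly these computations from scratch
with a caller-supplied seed and writes the resulting numbers to JSON.

## Known limitations

* Only pairwise (binary) exposure contrasts are supported; multi-arm
  studies are analysed as repeated pairwise comparisons against a common
  reference.
* Matching estimators are not provided; adjustment is by weighting.
* The Bross score uses the crude outcome risk ratio; outcome-adaptive or
  machine-learning prioritisation is out of scope.
* Proxy exclusion (step 2) is an explicit user-supplied list of feature
  identifiers or prefixes; no automatic detection of exposure/outcome
  proxies is attempted.
* Laboratory-type codes are used as presence/recurrence indicators only;
  measurement values are ignored by design.
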