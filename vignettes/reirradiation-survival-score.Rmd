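---
title: "Methods: actuarial point scores for palliative reirradiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actuarial point scores for palliative reirradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reradscore)
```

## Scope and model

`reradscore` packages the workflow by which a prognostic point score for
palliative reirradiation is derived from, and applied to, right-censored
survival data. The unit of analysis is one reirradiation course; survival
time is measured in months from the start of reirradiation, and patients
lost to follow-up are censored at last documented contact. A patient may in
principle contribute more than one course; courses are treated as
independent records, since no within-patient correlation structure is
observable in data of this kind.

The score itself is deliberately simple. For each of four prognostic
factors — performance status dichotomised at KPS ≤ 60, known liver
metastases, pleural effusion, and steroid use at the start of radiotherapy
— the package estimates the actuarial death rate at a fixed horizon in the
subcohort at each factor level, as `100 * (1 - S(t))` from the Kaplan–Meier
estimate, and converts it to points by dividing by ten. Variant 1 uses a
1-month horizon, variant 2 a 2-month horizon; the two horizons encode two
operational definitions of "too short a survival to benefit from
treatment". A patient's total is the sum over the four factors, and totals
map to four ordered risk groups. Patients with any missing score factor are
unassignable and are reported as such, never imputed: in palliative
practice an honest "cannot score" is safer than a silently imputed tier.

### Rounding: a reconstruction

The published form of the rule says only "death rate divided by 10", yet
the printed point values are clearly rounded: 15% becomes 1.5 points and
11% becomes 1 under the 1-month variant, while 39% becomes 4 and 49%
becomes 5 under the 2-month variant. Two simple rules are consistent with
every printed cell, and the package adopts them as the variants' rounding
conventions: variant 1 floors `rate / 10` to the nearest lower multiple of
0.5 (`floor(rate / 5) / 2`), variant 2 rounds `rate / 10` half-up to an
integer. Both are implemented in `assign_points()` and both are
non-decreasing in the rate, so the monotonicity of the underlying death
rates carries through to the points. This is a reconstruction — the
original rounding procedure is not documented — and is flagged as such
here; anyone preferring a different convention can post-process the
`rate_percent` column of a `point_table`.

### Risk-group boundaries

The four-tier boundaries (variant 1: 0, (0, 1.5], (1.5, 3], > 3; variant
2: ≤ 5, (5, 8], (8, 11], > 11) are shipped as fixed defaults in
`assign_risk_group()`, not searched for. Automatic cutpoint optimisation on
the derivation data would overstate separation; the package therefore
treats cutpoints as configuration. When a table is derived from data whose
death rates differ substantially from the published ones, the default
boundaries may collapse to fewer than four occupied groups; the pipeline
reports this and skips the stratification comparison rather than inventing
new boundaries.

## Survival machinery and its numerical choices

The estimation layer is written in the package rather than delegated, so
that every step of the score derivation is inspectable and testable against
independent oracles (the `survival` package serves as a cross-check in the
test suite, never as the implementation).

* **Kaplan–Meier** (`km_estimate()`): product-limit estimate over distinct
  death times with Greenwood standard errors. At tied times, deaths are
  processed before censorings — an individual censored at *t* is still at
  risk at *t*. This is the standard convention; it is stated explicitly
  because month-resolution data produce many ties.
* **Actuarial death rate** (`death_rate_at()`): interpreted as
  `1 − KM(t)` with the survival function right-continuous, so deaths at
  exactly the horizon count as dead. The life-table (actuarial-interval)
  estimator is a defensible alternative; at the precision at which rates
  are printed (whole percent) the two agree for data recorded at daily or
  finer resolution, and the Kaplan–Meier reading matches how the curves
  are generated in the first place. Horizons beyond the last observed
  follow-up return the last available estimate flagged `extrapolated`.
* **Log-rank** (`logrank_test()`, `pairwise_logrank()`): the pooled k-group
  statistic with hypergeometric variance, referred to the asymptotic
  chi-square distribution on k − 1 degrees of freedom. An exact permutation
  reference lives in the test suite (exhaustive enumeration at n = 6), not
  in the shipped p-values. Pairwise comparisons are uncorrected by default,
  matching common reporting practice in small prognostic-factor studies;
  Bonferroni and Holm flags are available.
* **Cox regression** (`cox_fit()`): Breslow tie handling, Newton–Raphson
  with step-halving, convergence when the partial log-likelihood changes by
  less than 1e-8 (at most 50 iterations), standard errors from the observed
  information. Breslow is the simplest tie approximation and is adequate at
  month-level precision; Efron weighting would change third-decimal digits
  in typical cohorts of this size. Monotone likelihoods (perfect
  separation) are detected by coefficient divergence and flagged
  non-converged rather than silently truncated. Converged fits satisfy the
  score equation to max-norm 1e-6 and are invariant to record order.
* **Model selection** (`univariate_screen()`, `backward_eliminate()`): the
  screen carries forward factors with a pooled log-rank p strictly below
  0.1. Backward elimination approximates the "backward conditional"
  selection of commercial statistics packages with likelihood-ratio removal
  tests at threshold 0.10 (that family of defaults): the term with the
  largest removal p is dropped while that p is at or above the threshold,
  refitting after each removal. The conditional statistic itself is
  undocumented; the likelihood-ratio form is the closest principled
  analogue. Multi-column terms — the three KPS bands enter screening as a
  3-level factor via two indicators — are removed or retained jointly. The
  complete-case set is fixed on the full starting model so that all nested
  comparisons use the same records, mirroring listwise deletion. KPS is
  screened as three bands (90–100, 70–80, ≤ 60) but scored as the ≤ 60
  dichotomy, the granularity at which the point table is defined. Boundary
  semantics follow from the removal rule: with `removal_p = 0` every term
  is removed (any p ≥ 0) and the null model is returned with a warning;
  with `removal_p = 1` nothing is removed unless a removal p equals
  exactly 1.

## The synthetic-cohort generator

No patient-level data accompany the methodology, so the package ships a
seeded generator (`simulate_cohort()`) whose defaults emulate the study
conditions of a dedicated palliative radiotherapy service: covariate
prevalences of 30% KPS ≤ 60, 34% KPS 70–80, 54% steroid use among known
(20% missing), 22% liver metastases, 7% pleural effusion, and a
prostate-led primary-site mix. Survival follows a proportional-hazards
exponential model (Weibull shape exposed as configuration) whose baseline
median, 18.3 months for the fully favorable reference pattern, and log
hazard ratios are calibrated from reported group-wise median survivals
using the exponential identity that the hazard ratio of two groups is the
inverse ratio of their medians (e.g. `log(18.3/2.1)` for KPS ≤ 60,
`log(12.2/3.6)` for steroids). Administrative censoring draws a censoring
time uniform on (0, 30) months, the mechanism implied by uniform accrual
over a 30-month window analysed at its close; the observed follow-up
distribution of the original service is not targeted.

Two simplifications are explicit. First, covariates are generated
independently, because only marginal frequencies are reported; in real
cohorts the adverse factors cluster (steroid use accompanies poor
performance status), so the generator's marginal death rates at short
horizons run higher than the published per-level rates when all hazard
ratios act at once. Tests that need exact per-level rates therefore use
`planted_rate_cohort()`, which plants a known cumulative death probability
at the horizon per factor level (exponential with rate `−log(1−p)/t`, no
censoring) and is verified against its binomial sampling distribution.
Second, the hazard-ratio calibration from marginal medians overstates
conditional effects for the same reason; it is a deliberate, documented
choice of a simple one-line calibration over an unidentifiable joint fit.
Consequently, passing tests on synthetic cohorts demonstrate that the
machinery recovers what was planted — not that the generator reproduces any
specific clinical cohort.

## What the tests establish, and at what scale

The suite tests each layer against an independent oracle: parsing by
round-trip on random cohorts; Kaplan–Meier against the empirical survivor
function (no censoring) and against `survival::survfit` (with censoring);
the log-rank statistic against `survival::survdiff`, an exhaustive
6-patient permutation enumeration, and a 2000-replicate null calibration
(n = 60 per cohort, 5% ± 3 Monte-Carlo SE); Cox estimates against a
grid-search maximiser of a naively coded partial likelihood (agreement to
1e-4), against `coxph(ties = "breslow")`, and by parameter recovery of
log 2 within 3 SE at n = 1000; selection by planted-factor recovery
simulations (hazard ratio 3–4, 60–200 replicates); score derivation by
recovering all sixteen published point-table cells from planted-rate
cohorts at 20 000 patients per level, where the binomial standard error of
a rate is about 0.35 percentage points and rounding absorbs it; and
stratification by recovering strictly ordered medians from planted
four-tier cohorts (medians 24/10/3/1 months, 100 per group, 200
replicates, ≥ 95% success). These problem sizes keep the full suite to a
few minutes while leaving comfortable statistical margins.

## Known limitations

The package derives and applies scores; it does not validate them
clinically. Cohort-specific published results (overall and group-wise
medians, pairwise p-values, group sizes) require the original 87-course
dataset, which was never deposited, and are therefore out of reach of any
reimplementation; the test suite substitutes the parameter-recovery
properties above. No calibration measures (c-index, Brier score), no
time-varying covariates, no proportionality diagnostics, no stratified or
weighted log-rank variants, and no automatic cutpoint selection are
provided. The SPS comparator is implemented in its three-variable form
only.
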