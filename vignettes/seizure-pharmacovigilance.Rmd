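---
title: "Reporting-odds and time-to-onset analysis of drug-induced seizures in spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting-odds and time-to-onset analysis of drug-induced seizures in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaderpv)
```

## The problem

Clozapine is the antipsychotic of choice for treatment-resistant
schizophrenia and, among antipsychotics, carries an unusually high seizure
risk. Seizures are too rare for clinical trials to characterize their risk
factors, so hypothesis generation falls to spontaneous reporting systems
(SRS) — case-only databases such as Japan's JADER, organized as four
relational tables (DEMO demographics, DRUG drug records, REAC coded adverse
events, HIST medical history) keyed by a case identification number.

An SRS has no denominator: it holds only reports of adverse events. The
comparison this package implements is therefore within-drug
disproportionality — among reports that involve the study drug, are
seizure reports over-represented at a given covariate level relative to
reports of other adverse events? — plus a time-to-onset analysis of the
seizure reports themselves.

## The model

### Case definition

A report is a *seizure case* when any of its REAC preferred terms belongs
to a Standardized MedDRA Query term set — in practice the narrow-scope
convulsions SMQ (20000079, 101 preferred terms). The same term set applied
to the HIST table defines a *history of convulsive disorder*. MedDRA is
licensed, so the package bundles only a 10-term demonstration subset
(`jaderpv_example("smq_convulsions_demo.txt")`); real analyses supply the
full term list as a plain text file.

### Adjusted reporting odds ratios

Among study-drug cases, a multivariate logistic regression models

```
seizure vs other adverse event ~ sex + age + dose + polypharmacy +
                                 lithium + fluvoxamine + antiepileptics +
                                 convulsive history
```

with treatment coding: sex (male reference), age band (29 and younger
reference; 30–39, 40–49, 50–59, 60+), study-drug dose (low < 200 mg/day
reference; medium 200–400, the closed interval; high > 400), antipsychotic
polypharmacy (any other listed antipsychotic), lithium (no use reference;
low ≤ 600 mg/day; high > 600), fluvoxamine, antiepileptic agents
(valproate, carbamazepine, lamotrigine, clonazepam, diazepam; agents
started after seizure onset count as non-concomitant), and history of
convulsive disorder. The exponentiated coefficients are adjusted reporting
odds ratios (aROR) with two-sided 95% Wald intervals
`exp(b ± 1.959964·SE)`; crude RORs from 2×2 tables (with the
Haldane–Anscombe 0.5 correction for zero cells) are available for
single-factor screens.

Cases with unknown sex, unknown or non-numeric age (the source bands age
in decades; labels like "adult" are unusable), unknown study-drug dose, or
lithium use with unknown dose are excluded before fitting, in that fixed
order, each case attributed to the first failing rule. The
`exclusion_ledger` records the counts and always satisfies
`n_input = n_retained + sum(exclusions)`.

### Time-to-onset

For seizure cases with complete dates, the onset day is
`(onset date − earliest complete study-drug start date) + 1`, so a
same-day onset is day 1 and every time is positive, as Weibull support
requires. Days beyond the 1,095-day analysis window are excluded, as are
incomplete or inverted date pairs. The sample is summarized by its median
and interquartile range (linear interpolation between order statistics,
`quantile` type 7) and by the maximum-likelihood fit of the Weibull
density f(t) = (β/α)(t/α)^(β−1) exp(−(t/α)^β), maximized over
(log α, log β) by BFGS with Wald intervals from the observed information on
the log scale, back-transformed. The shape CI classifies the hazard:
CI containing 1 (inclusive) → random failure (constant hazard); lower
limit > 1 → wear-out (increasing); upper limit < 1 → early failure
(decreasing).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dose_breaks` | 200, 400 mg/day | study-drug band edges; both edges fall in the medium band |
| `lithium_break` | 600 mg/day | lithium low/high edge |
| `dose_rule` | `"max"` | reconciliation of several dose records per case (`max`/`first`/`mean`); maximum reflects peak exposure |
| `sex_reference` | `"male"` | reference sex level (source figures do not pin it down, so it is configurable) |
| `window_days` | 1095 | time-to-onset analysis window |
| `day_convention` | `"plus1"` | onset day counting; `"halfday"` scores the raw difference with same-day onset as 0.5 |
| `quartile_type` | 7 | quantile algorithm, fixed for bit-reproducible summaries |

The critical value 1.959964 is fixed rather than recomputed so that output
is bit-stable across platforms.

## What the simulator emulates

`simulate_jader()` draws reports with decade-banded ages (including a
configurable fraction of non-numeric labels), the three drug-involvement
categories, mg/day doses inside each band, complete/partial/missing dates,
and a seizure outcome drawn from the logistic model at planted log odds
(`default_true_beta()`: the intercept −3.0 puts the marginal seizure
fraction near 11% of study-drug reports, matching the scale of published
cohorts; the effects are the published aROR profile). Seizure cases get an
onset day drawn from a Weibull law — `paperlike_config()` plants
α = 193 days, β = 1.0, putting the median near 134 days with a constant
hazard; the IQR-implied shape would be nearer 1.1, but a shape of 1 is what
a constant-hazard (random failure) onset profile means, and the median is
honoured exactly — rounded up to a whole day and anchored to the drug start
date. Missingness is applied after outcome generation, completely at
random; the exclusion fate each mask implies is recorded in the ground
truth by construction, so ledger counts, cohort covariates and onset
samples can be checked exactly.

What it deliberately does not emulate: reporting dynamics (stimulated
reporting, under-reporting trends), duplicate reports, free-text dose
strings, and non-MCAR missingness. Complete-case analysis is unbiased
under MCAR; real spontaneous reports surely violate that, so passing
recovery tests here validates the estimator arithmetic, not robustness to
informative missingness.

## Numerical choices and degenerate inputs

* Logistic fitting is iteratively reweighted least squares
  (`stats::glm.fit`) with tolerance 1e−10 and at most 100 iterations; the
  covariance is the inverse observed information at the optimum. The
  design is rank-screened first (collinear columns are a named error), and
  separation — flagged by `glm.fit` or by fitted probabilities within
  1e−10 of the boundary — marks the fit non-converged with a warning
  rather than reporting silent estimates. No Firth correction is applied:
  the estimate mirrors ordinary logistic aROR practice.
* The Weibull fit starts from the moment estimate
  β₀ = (π/√6)/sd(log t), optimizes with `reltol` 1e−12, and rejects
  samples with n < 3 or all-equal times (the shape diverges). Likelihood
  overflow during line search returns a large penalty instead of NaN.
* Zero cells in a 2×2 table either receive the 0.5 correction or yield an
  explicitly undefined estimate — never an exception.
* Partial dates are kept partial at ingest and only judged at analysis
  time; an onset before drug start is treated as a data error and counted
  with the missing-date exclusions.
* Histogram bins are half-open `[kw, (k+1)w)` and padded to the full
  window so histograms align across samples.

## Design choices where the method description is open

* **Earliest matching event date** defines seizure onset when a case has
  several seizure terms: one onset per case is needed and earliest is
  conservative.
* **Maximum dose** reconciles multiple study-drug records (peak exposure);
  the rule is configurable because nothing in standard practice pins it
  down.
* **First-failing-rule attribution** makes the exclusion ledger
  deterministic under the fixed rule order.
* **Antiepileptics with partial start dates count as concomitant**: a
  partial date is no evidence of post-onset initiation.
* **The lithium unknown-dose exclusion applies only to lithium users**;
  non-users are "no use", not unknown.
* **Day + 1 convention** for onset times, with the half-day alternative
  available; conventions differ between analysis systems and the choice is
  visible in the config.

## Known limitations

* Day-resolution dates quantize onset times upward (ceiling), which
  biases the continuous-density Weibull shape estimate by about +1% at the
  default onset scale; excluding the window overrun and then fitting an
  untruncated density adds roughly another +1.7%. Both effects are far
  inside the shape CI at realistic sample sizes (a few hundred onset
  times, CI half-width ≈ 0.15) but become visible in simulations with
  many thousands of onset times, where a planted constant hazard can be
  classified as wear-out. An interval-censored, truncation-aware
  likelihood would remove this at the cost of departing from standard
  Weibull-shape-parameter practice.
* Wald intervals misbehave with sparse cells (few exposed cases); rare
  covariates such as fluvoxamine need large samples before their aROR is
  stable.
* The aROR compares seizure reports to other adverse-event reports of the
  same drug; it is not a risk ratio and carries all the usual SRS caveats
  (no denominator, reporting bias).

## Problem sizes used in the validation suite

The bundled tests run the estimator-recovery checks at 200 simulated
cohorts of 2,000 reports (logistic CI coverage), 500 onset samples of 222
times (shape CI coverage), simulations of 20,000–30,000 reports for
consistency checks, and one 100,000-report qualitative reproduction of the
published profile; these sizes give Monte-Carlo error comfortably inside
the asserted bands while keeping the suite quick on a laptop.
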