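# jaderpv

Pharmacovigilance analysis of drug-induced seizures in spontaneous
adverse-event reports, built around the four-table layout of Japan's JADER
database (DEMO demographics, DRUG drug records, REAC coded events, HIST
medical history, keyed by a case identification number).

Spontaneous reporting systems hold only adverse-event reports — there is no
exposed population to divide by — so risk-factor screening is done by
disproportionality *within* the reports of one drug. For a study drug
(clozapine by default) the package:

1. **reads and joins** delimited DEMO/DRUG/REAC/HIST dumps with a
   configurable column mapping (the real source uses Japanese headers),
   collecting unmatched child rows into an orphan report;
2. **defines seizure cases** by matching REAC preferred terms against a
   Standardized MedDRA Query term set (narrow-scope convulsions,
   SMQ 20000079), and a history of convulsive disorder by the same terms in
   HIST;
3. **builds the analyzable cohort**, excluding cases with unknown sex,
   unknown or non-numeric age, unknown study-drug dose, or lithium use with
   unknown dose — in that order, with an auditable exclusion ledger;
4. **estimates adjusted reporting odds ratios** (aROR) from the logistic
   model

   `seizure ~ sex + age band + dose band + antipsychotic polypharmacy +
   lithium + fluvoxamine + antiepileptics + convulsive history`

   with two-sided 95% Wald intervals `exp(b ± 1.959964·SE)`, plus crude
   RORs `ad/bc` from 2×2 tables with the Haldane–Anscombe correction;
5. **characterizes time-to-onset** of the seizure reports: onset day =
   (event date − earliest complete drug start date) + 1, 1,095-day window,
   median/IQR, and a maximum-likelihood Weibull fit whose shape β reads out
   the hazard: CI(β) ∋ 1 → random failure (constant hazard), lower limit
   > 1 → wear-out, upper limit < 1 → early failure;
6. **simulates** JADER-shaped dumps with known ground truth
   (`simulate_jader()`), so every stage above can be validated against
   planted covariate effects, onset laws and missingness — no database
   download needed.

The bundled convulsions term list is a 10-term demonstration subset; real
analyses supply the licensed 101-term SMQ file (plain text, one term per
line).

## Worked example

```r
library(jaderpv)

sim   <- simulate_jader(sim_config(n_cases = 5000, seed = 2024))
cases <- filter_drug_cases(cases_from_sim(sim), "clozapine")
query <- read_term_list(jaderpv_example("smq_convulsions_demo.txt"))
flags <- flag_cases(cases, query)

built <- build_cohort(cases, flags)
built$ledger
#> <exclusion_ledger> 1201 cases in, 807 retained
#>   unknown_sex                27
#>   unknown_age_or_nonnumeric  60
#>   unknown_cloz_dose          299
#>   unknown_lithium_dose       8

adjusted_ror(built$cohort)$effects
#>                           label     or ci_low ci_high       p ...
#>              medium dose vs low  6.225  2.237  17.321 4.6e-04
#>                high dose vs low 23.306  8.510  63.830 9.0e-10
#>      antipsychotic polypharmacy  2.145  1.247   3.691 5.8e-03
#>            antiepileptic agents  0.491  0.256   0.941 3.2e-02
#>  history of convulsive disorder  8.700  3.095  24.458 4.1e-05
#>  ...

smp <- onset_days(cases, flags)
onset_summary(smp)          # median 122 d, IQR 46-260 at this seed
fit_weibull(smp)
#> <weibull_fit> n = 103
#>   scale alpha = 172.33 days (95% CI 140.49-211.37)
#>   shape beta  = 0.993 (95% CI 0.850-1.160)
#>   failure type: random
```

Reading: seizure reporting rises steeply with dose band and with a
convulsive history, falls under concomitant antiepileptics, and the onset
hazard is constant over the three-year window — the shape CI includes 1, so
seizures are a "random failure" adverse event: monitoring cannot safely
stop after an early high-risk phase. (At this small simulated size the
dose-band intervals are wide; point estimates stabilize toward the planted
values as `n_cases` grows.)

A file-based run of the same pipeline, driven by a YAML config, is
available through `run_simulate()` / `run_profile()` / `run_tto()` /
`run_all()`, which write the cohort table, exclusion ledger, effect table,
onset summary and histogram as CSV/JSON.

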