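---
title: "Measuring the quality of patient-generated symptom-diary data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quality of patient-generated symptom-diary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinodiary)
```

## The problem

Daily electronic diaries let allergists follow rhinitis symptoms through a
pollen season, but the data arrive unsupervised. A patient can be
perfectly *adherent* — an entry every day — while investing no effort in
the entries themselves, for instance by re-entering yesterday's answers.
Classical careless-responding screens (response times, infrequency items,
within-questionnaire inconsistency) target long one-off questionnaires
and transfer poorly to a 56-day stream of ten taps a day. `rhinodiary`
takes the alternative route: compute summary statistics *of the score
trajectory itself* and ask which of them are associated with adherence to
recording, on the hypothesis that patients who record more faithfully
also record more accurately.

## Scores and their unit steps

Three daily indices are built from the item-level diary
(see `?rtss`, `?csms`, `?vas_value`): RTSS (sum of six 0–3 grades,
0–18), CSMS (mean grade 0–3 plus a stepwise 0–3 medication score, 0–6)
and the VAS (0–10). Every trajectory carries its unit step S — the
smallest nonzero move the score can make: 1 for RTSS and VAS, 1/6 for
CSMS. S matters because the intravariation index normalises an
individual's range by it, putting scores of different granularity on a
common "number of steps" footing.

The medication hierarchy (antihistamine 1, nasal steroid 2, systemic
steroid 3, maximum when combined) follows the standard combined-score
convention; only the drug classes, not their weights, are fixed by the
diary format, so the weights are exposed as `med_weights` for sensitivity
analyses. RTSS is the plain sum of the six grades — its 0–18 range forces
that; there is no published item weighting.

## Adherence

`patient_adherence()` is deliberately boring: recorded days inside the
prescribed window over prescribed days, times 100. Three conventions are
worth making explicit because they change printed numbers:

- the 80% high/low threshold is *inclusive* (exactly 80% is "high");
- the cohort "average adherence" is the pooled ratio
  Σ recorded / Σ prescribed — when windows differ across patients this is
  not the mean of the individual percentages, so both are provided
  (`pooled_adherence()`, `mean_individual_adherence()`);
- records dated outside the window are excluded from the numerator and
  counted in `excluded_out_of_window`, never silently dropped.

Delayed starts and early stops of three days or more are flagged
(`start_end_deviation()`); the three-day rule mirrors the reminder
cascade of diary apps, which escalates after the third missed day.

## The four quality indices

All four are per-patient functionals of one score trajectory
(`trajectory_quality()`); undefined values are `NA` and are excluded
from cohort averages with a logged count, never imputed as zero.

| index | definition | undefined when |
|---|---|---|
| intravariation index | `pctVar / rVAR`; `pctVar` = % of consecutive-day pairs with a change, `rVAR` = (max − min)/S | no pairs |
| % zero values | 100 · #{yₜ = 0}/T | T = 0 |
| coefficient of variation | 100 · SD/mean, SD with n − 1 | T < 2 or mean = 0 |
| % changes in trend | label each pair's difference +/0/−; % of successive labels that differ, denominator n_pairs − 1 | fewer than 2 pairs |

A constant series has `rVAR = 0` and is assigned an intravariation index
of 0 (no variation), not a division error.

### Design choices that the definitions leave open

These were genuinely open and are all exposed as arguments; defaults are
the package's choices.

- **Pairing across gaps.** "Two consecutive days" is read literally:
  pairs form only on adjacent calendar dates (`mode = "calendar"`), so a
  recording gap contributes no pair. `mode = "record"` pairs successive
  records regardless of gaps, for data known to be dense.
- **rVAR variant.** The range in unit steps is `(max − min)/S`. A
  published variant adds one step, `(max − min + S)/S`; it is available
  as `rvar_plus_one = TRUE` (it also removes the constant-series special
  case). The plain form is the default because it is the form stated in
  running text rather than a footnote whose typography is ambiguous.
- **Trend mode.** The default counts *transitions between successive
  difference signs* — a construct distinct from the intravariation
  numerator. The alternative reading, the percentage of nonzero
  differences, is available as `trend_mode = "nonzero_diff"` but
  duplicates `pctVar`.
- **SD denominator** n − 1 (the usual sample estimator); **IQR** as
  25th/75th percentiles with linear interpolation
  (`stats::quantile()` type 7); **95% CIs** in the cohort summary are
  t-based, mean ± t₀.₉₇₅,ₙ₋₁·SE. None of these is fixed by the index
  definitions; all are stated here so printed tables are reproducible.

### Numerical conventions

CSMS values are k/6 in floating point, so "changed vs unchanged" and
"zero vs nonzero" use an absolute tolerance of 1e-9 — far below the
smallest grid step (1/6) and far above accumulated rounding error.
Trajectory constructors enforce the S-grid at the same tolerance, so
off-grid values fail fast instead of corrupting `pctVar`.

## Group comparison

For each score × index, per-patient values are compared between
adherence groups with a two-sided Mann–Whitney U test: exact when the
combined sample is ≤ 20 without ties, otherwise the normal approximation
with tie and continuity correction. Tables print medians (IQR) per
group. P-values are raw; twelve tests are reported and readers should
treat the table as exploratory, which is also why the test suite checks
the *pattern* of significance rather than any single p-value. Spearman's
ρ relates per-patient mean scores (asymptotic p, since ties among means
are routine).

## What the synthetic cohort emulates

`synthetic_config()` states a study world once; its defaults are not
tuning knobs:

- **101 patients, 56-day window** (2016-05-04 … 2016-06-28), matching a
  peak-grass-season monitoring campaign; pollen is a Gaussian seasonal
  kernel peaking mid-window (day 28, width 12) with multiplicative
  log-normal day-to-day noise (sd 0.35), capped at 199 grains/m³.
- **Symptoms**: latent burden = sensitivity × relative pollen + daily
  noise; each of the six items adds its own noise and is cut at ordered
  thresholds (0.25/0.55/0.85) into grades 0–3. Sensitivity is log-normal
  (sdlog 0.5), giving the wide between-patient severity spread real
  cohorts show.
- **Medication**: per-class logistic in the burden with a persistence
  bonus for yesterday's use — systemic steroids rare, antihistamines
  common.
- **VAS**: a saturating monotone map of burden plus reporting noise,
  rounded and clamped to 0–10.
- **Recording**: each patient draws a daily recording probability from a
  two-component Beta mixture (65% "high" class centred ≈ 0.93, else
  centred ≈ 0.62), plus a 9% / 12% chance of a ≥3-day delayed start /
  early end. This reproduces the qualitative adherence spread
  (roughly two thirds of patients above 80%, minima well below it).
- **Behaviour**: a patient is either *accurate* or *carry-forward*; a
  carry-forward responder copies the entire previous recorded
  questionnaire (all grades, medication flags and VAS) with per-day
  probability q = 0.8. With `link_behavior_to_adherence = TRUE`
  (default) the carry-forward prevalence is 0.7 in the low-adherence
  class and 0.1 in the high class; with the link severed it is 0.3
  everywhere — the null world used for type-I checks.

All randomness flows through one seed; `generate_cohort()` is
byte-reproducible and returns ground-truth labels and a manifest.

What the generator does **not** emulate: medication plans configured per
patient, weekends/weather in recording behaviour, parental assistance
effects in children, within-day entry times, or any calibration of index
*levels* to a real cohort. A green simulation test therefore establishes
that the pipeline recovers the qualitative adherence–quality structure
it was pointed at — not that real diaries have these index values.

## Known limitations — and two honest red tests

The acceptance suite runs 100 simulation replicates of the default world
and 100 of the null world. Two of its assertions fail, deliberately left
red because they reveal properties of the indices, not defects of the
code:

1. **The indices are not adherence-invariant even under the null.** With
   behaviour independent of adherence, rejection rates for % zeros and
   CV sit at the nominal 5%, but the intravariation index and the trend
   index reject in roughly 8–15% of replicates. The mechanism is that
   both depend on the number of recorded days: rVAR (an observed range)
   grows with T, deflating IVI for high-adherence patients; and
   adjacent calendar-day pairs share a value, so successive difference
   signs are negatively autocorrelated — recording gaps break that
   overlap, mechanically lowering the trend index for sparser
   recorders. Any adherence-group comparison of these two indices is
   therefore partly confounded by adherence itself; a length-matched or
   length-corrected comparison would be needed to isolate behaviour.
2. **Whole-questionnaire copying is not selective for the trend index.**
   Under the linked default world, carry-forward copying suppresses the
   IVI numerator at least as strongly as it suppresses trend
   transitions, so IVI separates the adherence groups in nearly every
   replicate and % zeros is affected in a sizeable minority. The
   trend index remains the most strongly and consistently associated
   statistic (significant on all three scores in 100% of replicates,
   higher in the high-adherence group), but the *exclusive* selectivity
   reported from real data does not emerge from a pure copying
   mechanism — real insufficient-effort behaviour is evidently richer
   than verbatim repetition.

Both points are verified by the acceptance tests themselves
(`tests/testthat/test-acceptance.R`, criteria 4b/4c) and documented in
the repository's decision ledger.

Other limitations: the reader rejects partially blank rows by default
(the capture app forced complete questionnaires, so partial rows signal
corruption — `partial = "drop"` relaxes this); per-patient windows are
supported but no attempt is made to infer windows from the data; and no
multiplicity correction is applied anywhere, by design.
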