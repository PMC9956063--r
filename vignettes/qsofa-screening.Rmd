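---
title: "Evaluating prehospital plus ED qSOFA for sepsis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating prehospital plus ED qSOFA for sepsis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsofascreen)
```

## The screening question

The quick Sequential Organ Failure Assessment (qSOFA) awards one point
each for systolic blood pressure <= 100 mmHg, respiratory rate >= 22
/min, and altered mental status (AMS, operationalized here as Glasgow
Coma Scale <= 14), giving a 0--3 bedside score.  Screened at >= 2 on ED
arrival it is specific but insensitive for sepsis, which is why current
sepsis guidance recommends against using it as a standalone screen.
Patients arriving by ambulance, however, carry a *second* measurement
set: the vitals recorded by ambulance staff before arrival.  This
package evaluates whether the **combined qSOFA** — the sum of the
prehospital and ED totals, range 0--6, screened at >= 3 — recovers
sensitivity that the ED score alone leaves on the table, without
sacrificing the score's bedside simplicity.

The package implements the complete retrospective analysis as a
pipeline:

1. **Cohort building** — adults (>= 18 years) with suspected infection
   (chief complaint of fever, ED body temperature >= 37.5 °C, or an ED
   infection diagnosis), excluding trauma, cardiac arrest, death on
   arrival, transfer to another hospital, and records with six or more
   of the seven vital parameters (sBP, dBP, HR, RR, BT, GCS/AMS, SpO2)
   missing at either stage.  Every input record is accounted for exactly
   once in the flow summary.
2. **Outcome labeling** — a rule-based clinical surveillance definition
   of sepsis (see below), a vasopressor-plus-lactate rule for septic
   shock, and recorded disposition for in-hospital mortality.
3. **Imputation** — iterated random-forest imputation of the missing
   vitals.
4. **Scoring** — prehospital, ED and combined qSOFA.
5. **Evaluation** — c-statistics with DeLong variance, paired DeLong
   tests against the ED score, per-cutoff sensitivity / specificity /
   PPV / NPV with Wilson intervals, the stage-transition table, and the
   *added capture*: outcome-positive patients flagged by the combined
   score but negative on the ED score.

Because no patient-level data are deposited with the study this design
follows, the package ships a synthetic cohort generator calibrated to
the study population's published marginals; every pipeline stage is
exercised end to end against it.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` draw a cohort of ambulance-arrival
suspected-infection patients:

* **Latent disease state.** Each patient is septic with probability
  `sepsis_prev` (default 0.15); septic patients progress to septic shock
  with probability `shock_prev / sepsis_prev` (defaults 0.06 / 0.15).
  In-hospital death has relative risk 1 / 5 / 12 across the
  none / sepsis / shock states, with the baseline solved so the marginal
  equals `mortality_prev` (default 0.09).
* **Continuous vitals.** Each of sBP, dBP, HR, RR, BT, SpO2 is drawn at
  both stages from a truncated normal located at the reference cohort's
  median with scale IQR/1.349 (physiologic truncation bounds), shifted
  additively for septic patients (`sepsis_shift`, scaled by
  `shock_shift_mult` = 1.6 for shock).  Within a patient, the
  prehospital and ED values of the same vital share a Gaussian copula
  with correlation `stage_correlation`.
* **AMS / GCS.** Only the AMS proportion is published, so GCS is a
  two-part mixture: GCS 15 with probability 1 − p, else an integer in
  3--14 weighted toward mild depression.  p is `ams_base` on the logit
  scale plus `ams_shift` for septic patients; the same latent copula
  correlates the two stages.
* **ICU course.** All septic patients (and a configurable fraction of
  the rest) carry the chart fields the surveillance labeler consumes
  (blood-culture day, antimicrobial days, vasopressor / ventilation
  initiation days, lactate, creatinine, bilirubin, platelets).  With
  `label_sensitivity = label_specificity = 1` (the default) these fields
  encode the latent state exactly, so the labeler's output can be
  checked against ground truth; lower fidelities simulate chart noise.
* **Missingness.** Per-cell MCAR at the published per-variable rates
  (2%--33%; AMS at ED arrival is the worst at 33%).  A MAR option
  multiplies the missingness odds for AMS patients and rescales to hold
  the marginal, for robustness experiments.

### Calibration of the defaults

The reference summary gives only marginals — medians/IQRs, AMS
proportions, outcome prevalences — and no joint law, so all joint
structure (the stage correlation, the sepsis shifts, the GCS mixture)
is a simulator choice.  The shifts and correlation were calibrated once
so that, at the defaults, the scores' discrimination for sepsis matches
the reference analysis: prehospital AUC 0.65, ED 0.67, combined ≈ 0.68
(Monte Carlo at n = 60,000).  `stage_correlation = 0.8` reflects that
the two measurements are under an hour apart; it also reproduces the
reference pattern in which the combined score adds only ~0.01--0.02 AUC
over the ED score while adding materially to sensitivity at its cutoff.
Two quantities the reference tables do not report were fixed at
clinically typical values: SpO2 location (median 96%) and SpO2
missingness (4--5%); SpO2 is not a qSOFA component, so neither affects
score calibration.

What the generator does **not** emulate: transport-time dependence of
the prehospital–ED relationship, physiologic time-series structure
within a stage, and any direct vital-sign pathway to death — mortality
acts only through the latent disease state, which caps the simulated
qSOFA-for-mortality discrimination (~0.60) below values seen clinically
(~0.69).  Passing tests therefore certify the pipeline's statistical
machinery on a cohort with the published marginal structure, not the
full joint behaviour of real patients.

## The surveillance definition of sepsis

Sepsis-3 defines sepsis through a SOFA increase of >= 2, which is hard
to score retrospectively.  The labeler instead implements the
chart-computable clinical surveillance rule: **presumed serious
infection** (a blood culture obtained *and* >= 4 qualifying
antimicrobial days) together with **>= 1 acute organ-dysfunction
criterion** within ± 2 days of the culture day —

* vasopressor initiation,
* mechanical-ventilation initiation,
* lactate >= 2.0 mmol/L,
* creatinine peak >= 2 × baseline (excluding end-stage renal disease),
* bilirubin peak >= 2.0 mg/dL and >= 2 × baseline,
* platelet nadir < 100 ×10³/µL with >= 50% decline from a baseline
  >= 100.

All thresholds and the window are named entries of
`surveillance_config()`, so a site-modified variant is a configuration,
not a code change.  Boundaries are inclusive (a lactate of exactly 2.0
qualifies).  Septic shock is not separately defined in the reference
analysis; the package's documented default is the Sepsis-3-consistent
rule *sepsis + vasopressor + lactate >= 2.0*.  In-hospital mortality is
taken from the recorded disposition, never inferred.

## Imputation

`impute_vitals()` implements missForest-style iterated conditional
imputation with `ranger` forests (defaults: 100 trees, <= 10 cycles,
least-missing column first, stop when the normalized change in imputed
values stops decreasing and keep the last improving fill).  Observed
cells are never modified; forest predictions are means of observed
responses and therefore stay inside each column's observed range; GCS
is imputed on its ordinal scale, then rounded and clamped to 3--15, and
AMS is derived afterwards as GCS <= 14.

Two faithfulness notes.  First, the predictor set includes the outcome
labels by default, mirroring the retrospective design this follows;
that choice leaks outcome information into imputed vitals and inflates
downstream discrimination slightly (the full-pipeline combined-qSOFA
AUC at n = 2407 runs ≈ 0.70 against the 0.688 scoring-law value;
set `include_outcomes_as_predictors = FALSE` to remove the leak).
Second, one completed dataset is the default — the analysis computes
one set of scores — with `n_datasets > 1` available for sensitivity
checks; pooling across datasets is intentionally out of scope.

## Evaluation machinery and numerical choices

* The **c-statistic** is computed as the Mann–Whitney pair statistic
  with ties counted ½; over an integer score this equals trapezoidal
  ROC integration, and the test suite asserts exact agreement with
  exhaustive pair counting.
* Its **variance** uses DeLong's structural components
  (`var(V10)/m + var(V01)/n`); the paired **DeLong test** uses the full
  component covariance, is antisymmetric, and returns p = 1 (with a
  warning if the AUCs differ) when the variance of the difference is
  numerically zero.  The implementation is cross-checked in tests
  against an independent ROC package and a jackknife.
* **Proportion CIs** default to the Wilson score interval — better
  behaved than Wald near 0/1 at these denominators — with
  Clopper–Pearson (`"exact"`) and Wald selectable.  The AUC CI is the
  DeLong normal interval clipped to [0, 1], with a logit-scale option.
* A predictive value with an empty denominator is reported `NA`, never
  0.  P-values are two-sided with no multiplicity adjustment, matching
  the reference analysis (α = 0.05).  Printed tables round to 2
  decimals.
* **Degenerate inputs** fail loudly: single-class labels, mismatched
  lengths, unknown stages, duplicate patient ids, and negative
  ICU-course values are errors, not silent results.
* **Tie-breaks / precedence.** Exclusion reasons are attributed in the
  fixed order age, no suspected infection, trauma, cardiac arrest,
  death on arrival, transfer, insufficient vitals; only the attribution
  (not cohort membership) depends on the order.  The fever clause of
  the inclusion rule is evaluated on the ED temperature by default and
  is configurable (`bt_stage = "pre"` / `"either"`), since the
  reference rule does not name the stage.

## Worked example

```{r example, eval = FALSE}
library(qsofascreen)

cfg <- run_config(simulate = sim_config(n_patients = 2407, seed = 1),
                  seed = 1)
res <- run_pipeline(cfg)
res$accuracy[["qsofa_combined.sepsis"]]
res$added_capture
```

At these settings the combined score's c-statistic for sepsis is ≈ 0.70
with a DeLong p < 0.01 against the ED score, and the added capture is
≈ 12% of septic patients — patients the ED screen alone would have
missed, picked up because their prehospital score carried forward.

## Problem sizes used in the checks

The package's own verification uses Monte Carlo sizes chosen to make
each property's sampling noise small relative to its tolerance:
calibration at n = 60,000; CI-coverage of the scoring-law AUC with a
truth from n = 120,000 and 100 replicate cohorts of n = 2407 (the
study's size); DeLong null size with 100 replicates at n = 300; the
masking experiment at n = 800.  The coverage property is evaluated with
missingness off: its estimand is the AUC implied by the generator's
conditional score law, and inserting the stochastic imputer into the
loop would shift that estimand (see the leakage note above) rather than
test CI coverage.

## Known limitations

* All joint-structure defaults are simulator choices; only the
  marginals are anchored to published values.
* The per-cutoff sensitivities and specificities of the synthetic
  cohort are emergent from that joint law and are not forced to match
  the reference tables (the generator is calibrated on the AUCs only).
* The MCAR default is an assumption; the reference analysis does not
  state a missingness mechanism.  The MAR switch covers one plausible
  alternative (AMS-dependent missingness), not MNAR.
* Free-text chief-complaint parsing, ICD coding, SOFA scoring and
  comparator scores (SIRS, NEWS) are out of scope.
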