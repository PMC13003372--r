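---
title: "Methods: validating early warning scores in patients aged 80 or older"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating early warning scores in patients aged 80 or older}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsbench)
```

## The problem

Early warning scores (EWS) convert a handful of bedside observations —
respiratory rate, SpO2, blood pressure, heart rate, temperature,
consciousness — into an additive point total via published band tables, and
are used in emergency departments to flag patients at risk of short-term
deterioration. Their derivation cohorts skew decades younger than today's ED
population, and physiology in the very old is blunted: an 85-year-old can be
gravely ill at a heart rate that would be unremarkable at 50. `ewsbench`
packages the full validation workflow for this question — do NEWS, NEWS2,
MEWS, REMS and IEWS still discriminate and calibrate for 24-hour death or
ICU admission in patients aged 80 or older? — as reusable, tested code,
exercised end to end on a synthetic cohort that emulates the population
structure of a large single-centre geriatric ED study (about 50 000
encounters, 2.4% deterioration prevalence, median age 85).

## The score engine

Each score is a declarative band table (`inst/extdata/definitions/*.json`):
per component an ordered list of closed intervals mapping the recorded value
to points, or a categorical map (AVPU, sex, oxygen flags). The engine is
generic; the definitions are data. Choices worth knowing:

* **Closed bands on the recorded value.** Published charts quote closed
  integer (or one-decimal, for temperature) bounds; validation checks that
  every component's bands cover its physiologic domain gap-free at that
  resolution and never overlap. The published MEWS chart writes `HR < 40`
  next to `41–50`; the fixture closes this to `<= 40` so integer coverage is
  exact.
* **NEWS2 SpO2 Scale 2** applies when the record carries the type-2
  respiratory-failure risk flag (confirmed COPD history); on-air and
  on-oxygen variants are separate band sets. For a flag-free record NEWS2
  equals NEWS by construction, and a property test enforces it.
* **MAP** is taken from the record when present, otherwise derived as
  `dbp + (sbp - dbp)/3` and rounded to the (integer) REMS band grid. REMS is
  its only consumer.
* **IEWS is a labelled synthetic stand-in.** The exact published IEWS point
  table was not available when the fixture was written, and its values are
  deliberately not guessed: `iews_synthetic.json` keeps the score's
  documented structure (NEWS2-style vitals bands plus age and sex points,
  with an age gradient that keeps rising past 74 where REMS flattens) and is
  calibrated so that an 80+ cohort lands near published summary medians
  (controls about 8, cases about 12). Results for "IEWS" characterise this
  stand-in, not the published score. Swap in a faithful transcription (one
  JSON file, no code change) before using IEWS substantively.
* **"New confusion" is not modelled**; V/P/U on the AVPU scale carries the
  consciousness points, because the emulated data dictionary records AVPU
  only.

Correctness is pinned two ways: a brute-force oracle in the test suite
re-scores ~10^4 random in-domain records by scanning every band of the raw
JSON linearly, and a monotone-dominance property checks that moving any one
vital into a higher-point band never lowers a total.

## The synthetic cohort

Only class-conditional marginals (medians and IQRs) and flag rates of the
emulated population are public, so the generator states a world rather than
resampling one:

* Outcome first: `outcome24h ~ Bernoulli(0.024)`.
* Each vital is drawn per class from a **two-piece (split) normal** matched
  exactly to the published median and quartiles, clamped to its physiologic
  domain and rounded to its resolution. The published case heart-rate cell
  is internally inconsistent (median outside its own IQR); the generator
  keeps the stated median 86 with a symmetric default IQR of 73–99, width
  comparable to the control IQR.
* Joint dependence comes from one latent severity factor per patient through
  a Gaussian copula: loading `latent_rho = 0.4` (chosen a priori as a
  moderate within-class correlation), signed so that "sicker" means higher
  HR/RR and lower SBP/SpO2/consciousness.
* **AVPU is primary, GCS consistent.** The published table reports controls'
  GCS as 15 (14–15) yet only 5.5% "not alert" — sampling GCS first and
  mapping to AVPU would make half the controls not alert and wreck the score
  distributions. The generator therefore samples AVPU from the per-class
  not-alert rates (splitting the not-alert mass 0.5/0.3/0.2 over V/P/U) and
  emits a GCS consistent with the level (A -> 14–15, V -> 13–14, P -> 9–12,
  U -> 3–8).
* Age is a split normal matched to median 85 (IQR 82–88) clamped to
  [80, 105]; MAP is derived from the generated pressures so the record
  invariant `dbp <= map <= sbp` always holds.
* `severity_shift` interpolates every case parameter between the control
  value (0) and the published case value (1, the default). It exists because
  the real joint distribution — hence the real AUROC — is unavailable;
  `severity_shift = 0` is an exact null generator used by the calibration
  property tests. It was not adjusted to meet any test.
* A `truth` column stores an approximate per-record deterioration
  probability (naive-Bayes posterior from the class-conditional marginals),
  for generative-recovery experiments.
* Missingness is injected MCAR per variable, capped below 5% (the emulated
  regime); rates at or above 5% are a configuration error.

What this world reproduces: the marginal Table-1-style structure, the
prevalence, and fair discrimination (score AUROCs land around 0.69–0.78
without tuning, against published 0.747–0.782). What it does not: the real
joint dependence (the control REMS median comes out 7 rather than the
published 6 — independent marginal tails contribute about one extra point),
temporal trajectories, readmissions, or any real missingness mechanism. A
green test therefore establishes that the *machinery* is correct in a
faithful world, not that the published point estimates are recovered.

## Missing data

Records missing more than 2 score parameters are excluded (boundary
inclusive: exactly 2 is retained). The rest are completed by chained
equations: each incomplete vital is regressed on age, sex, AVPU, the oxygen
flag and the other vitals; predictive-mean-matching (PMM) supplies values
from donors with similar predictions; `m = 20` chains are reduced to one
completed dataset because scoring consumes a single cohort. Two deliberate
departures from textbook PMM, both forced by the weak-signal regime
(conditional R² of any vital on the rest is only ~0.1 in this world):

* the donor pool scales with the data (1% of donors, at least 10) instead of
  the classical k = 5, and
* intermediate chained cycles use random donor draws, but each chain's
  *final* value is the donor-window mean. Averaging a few random draws from
  a tiny fixed pool leaves an irreducible donor-noise floor of order
  `(1/m + 1/k)` times the residual variance, which in this regime cancels
  the entire conditional signal; the window-mean reduction restores it, and
  the masked-recovery property (imputation RMSE at or below unconditional
  median fill, per variable) then holds across seeds.

Observed values are never altered; the outcome is never a predictor;
fixed seed implies an identical completed dataset.

## Discrimination

AUROC is the tie-corrected Mann–Whitney concordance; its variance and all
paired score comparisons use DeLong placement values. Ties get half credit
everywhere (the trapezoidal convention), which is what makes the
anti-symmetry property `auroc(s) + auroc(-s) = 1` exact for integer scores.

The age analysis computes AUROC in closed 5-year windows `[a, a+4]`
advancing by 1 year, plotted at window midpoints; windows with fewer than 10
events (default) are reported as absent, not zero, and excluded from the
trend fit. The trend is unweighted OLS of window AUROC on a restricted cubic
spline of midpoint age with 3 degrees of freedom — 4 knots at the
5/35/65/95th percentiles of the window centers (the standard placement; only
the df was specified) — with an F test against the intercept-only model. An
exactly constant series returns F = 0, p = 1 rather than 0/0. One honest
caveat, inherited from the procedure itself: overlapping windows share
patients, so window AUROCs are serially correlated and the OLS F test is
anti-conservative on real window series. The type-I-error acceptance check
therefore feeds the fitter independent-noise null series, which is the
regime in which the F test's nominal calibration is a well-defined claim.

## Calibration and classification

Predicted probabilities come from univariable logistic models (one per
score). Complete separation is detected and handled by a lightly
ridge-penalised IRLS refit, flagged in the result. Calibration is assessed
by:

* **Brier score** with patient-resampling bootstrap CIs (B = 2000 by
  default, seeded; tests scale B down and say so) and paired bootstrap p
  values against the constant-prevalence null model (Brier `p(1-p)`, which
  at the emulated 1233/50645 events is 0.0238) and against the
  best-calibrated score;
* **calibration slope/intercept** from a logistic recalibration of the
  outcome on the logit of the predicted probability (slope 1 = ideal, below
  1 = predictions too extreme), the convention that matches
  "slope < 1 indicates overfitting";
* equal-count **calibration bins** (10 by default, collapsing with a warning
  on tiny data).

Classification pins operating points to positive predictive value: the
threshold for a margin is the *smallest* integer cut-off t (positive iff
score >= t) whose empirical PPV meets the margin, scanned exhaustively.
Sensitivity/specificity/PPV/NPV carry Wilson 95% intervals (well-behaved at
the extreme proportions a 2.4% prevalence produces). A margin at or below
prevalence returns the minimum score (everyone positive already qualifies);
an unattainable margin is an explicit result, not an error. Precision-recall
curves integrate step-wise (average precision), with the prevalence as the
uninformative baseline.

## Component contributions

A gradient-boosted tree classifier over the union of all score inputs (age,
sex, HR, RR, SBP, MAP, temperature, SpO2, GCS, ordinal AVPU, oxygen and
COPD flags) is fitted per age stratum (80–86 vs 87 or older, identical
hyperparameters), and per-feature contributions are mean absolute SHAP
values, raw and normalized by the maximum (so exactly one feature scores 1
per stratum). Because no boosted-tree/SHAP library could be assumed
available at run time, both pieces are implemented here: a histogram-based
booster with the standard second-order gain and shrinkage (defaults: depth
3, 200 rounds, learning rate 0.1, L2 = 1, class-imbalance weighting by the
negative/positive ratio; all exposed in config), and tree-path-dependent
TreeSHAP in C++. TreeSHAP is validated in the tests against a brute-force
subset-enumeration Shapley oracle on small trees, and local accuracy
(attributions + expected value = margin, within 1e-6) is checked on every
call.

The stratum contrast reports, per feature, the difference in normalized mean
|SHAP| (older minus younger) with a two-sided nonparametric bootstrap p.
The models are fitted once per stratum; the bootstrap resamples patients'
per-feature |SHAP| rows within stratum and renormalises per resample.
Refitting the booster inside the bootstrap would be the literal reading of
"bootstrap tests on SHAP differences" but is neither computationally
plausible as the original procedure nor affordable here; the resampling
scheme tests the same null (no difference in normalized contributions) at
fixed models. No train/test split is used for attribution (attribution, not
generalisation, is the goal); a held-out AUROC diagnostic is available in
the tests. The stand-in IEWS caveat does not touch this module — it uses
raw variables, not score totals.

## Reproducibility

Every stochastic stage takes a seed; the pipeline fans a single global seed
out via `stage_seed = (seed * 7 + stage_index * 1001) mod (2^31 - 1)`.
Reports contain no timestamps, so a fixed config reproduces every artifact
byte for byte — an acceptance test asserts exactly that. All tables are
emitted as CSV plus a JSON metrics file and a manifest (config, package and
R versions, per-stage seeds).

## Known limitations

* The synthetic world matches marginals, not the real joint; absolute
  metric values (AUROCs, Brier scores, SHAP differences) are properties of
  the stated world and are not expected to equal the published ones.
* The IEWS fixture is a synthetic stand-in (above).
* The spline F test on real overlapping-window series is anti-conservative.
* MCAR is an assumption of convenience; the emulated study does not
  characterise its missingness mechanism.
* Single observations per encounter; no repeat-visit dependency, no
  temporal vitals.
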