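---
title: "ACLF-based risk stratification in acute variceal bleeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ACLF-based risk stratification in acute variceal bleeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avbaclf)
```

## The clinical question

Acute variceal bleeding (AVB) is a common, lethal decompensation of
cirrhosis. A subset of bleeding patients additionally meet the EASL-CLIF
definition of acute-on-chronic liver failure (ACLF) — acute
decompensation plus one or more organ failures — and carry a much higher
short-term mortality than patients with "mere" acute decompensation
(AD). This package implements the full analytical chain for asking how
much prognostic information the ACLF framework adds in AVB: score the
patient's first ICU day, diagnose and grade ACLF, and validate the
competing prognostic scores against 6-week (42-day) all-cause mortality,
the standard AVB endpoint.

## Scores and diagnostic rules

Six scores are implemented, all from first-day (worst-value) data:

* **CTP** (`compute_ctp()`): five components (bilirubin, albumin, INR,
  ascites, hepatic encephalopathy), each 1–3 points; classes A (5–6),
  B (7–9), C (10–15). We use the INR-based variant of the coagulation
  row (INR <1.7 / 1.7–2.3 / >2.3) because INR is the coagulation
  variable collected in the cohort schema; prothrombin seconds would be
  an equivalent alternative.
* **MELD** (`compute_meld()`): the classic UNOS formula
  \(9.57\ln C + 3.78\ln B + 11.2\ln I + 6.43\) with floors at 1.0,
  creatinine capped at 4.0 (forced to 4.0 on renal replacement
  therapy), rounded to an integer. A precomputed MELD column, when
  supplied, takes precedence, which reproduces workflows where MELD is
  distributed with the source database. We assume the classic formula
  rather than the 2016 sodium revision because MELD-Na is computed
  separately from MELD.
* **MELD-Na** (`compute_meld_na()`): MELD + 1.59 (135 − Na), sodium
  clamped to [120, 135] mEq/L, so the correction is never negative.
* **CLIF-OF** (`compute_clif_of()`): six organ systems scored 1–3,
  total 6–18. The subscore-3 boundaries coincide with the organ-failure
  definitions below for five organs; the kidney keeps the published row
  (<2 / 2–<3.5 / ≥3.5 mg/dL or RRT), whose failure region begins inside
  subscore 2 — in the original scale the kidney is the one organ failed
  from subscore ≥ 2, and the CLIF-C ACLF score depends on the published
  row, so we do not redefine it.
* **CLIF-C ACLF** (`compute_clif_c_aclf()`):
  \(10\,[0.33\,\mathrm{CLIFOF} + 0.04\,\mathrm{Age} + 0.63\ln \mathrm{WBC} - 2]\),
  defined only in the ACLF stratum.
* **CLIF-C AD** (`compute_clif_c_ad()`):
  \(10\,[0.03\,\mathrm{Age} + 0.66\ln \mathrm{Cr} + 1.71\ln \mathrm{INR} + 0.88\ln \mathrm{WBC} - 0.05\,\mathrm{Na} + 8]\),
  defined only in the AD stratum.

Nothing is rounded except MELD (integer by definition) and report
formatting, so formula outputs are exactly testable.

Organ failures (`assess_organ_failures()`): liver, bilirubin ≥ 12 mg/dL;
coagulation, INR ≥ 2.5; kidney, creatinine > 2 mg/dL or RRT;
circulation, vasopressor requirement; respiration, PaO2/FiO2 ≤ 200 or
SpO2/FiO2 ≤ 214 or mechanical ventilation for reasons other than airway
protection in the absence of HE III–IV; brain, HE III–IV. When both
oxygenation ratios are present PaO2/FiO2 takes precedence (the arterial
ratio is the reference measurement); a missing ratio is never read as a
failure.

Grading (`grade_aclf()`): ≥3 failures → grade 3; exactly 2 → grade 2; a
single failure → grade 1 only if (1) it is the kidney, or (2) it is
liver/coagulation/circulation/respiration accompanied by creatinine
1.5–1.9 mg/dL and/or HE I–II, or (3) it is the brain accompanied by
creatinine 1.5–1.9 mg/dL; otherwise AD. Interpretation choices: the
creatinine band is the closed-below interval [1.5, 2.0) intersected
with not-kidney-failed (values in (1.9, 2.0] fall outside the literal
band and are excluded; the ambiguity affects a measure-zero sliver of
continuous data); "and/or" is a logical OR; "mild to moderate HE" means
West Haven I–II (covert/minimal HE is not counted — HE grading is
subjective at the margin, and I–II is the literal reading); kidney
failure via RRT with low creatinine still satisfies the single-kidney
rule. The grading function is verified against an independently coded
brute-force oracle over the complete truth table of failure
combinations × creatinine strata × HE strata.

## The synthetic cohort generator

Real cohorts of this kind come from credentialed critical-care
databases that cannot be redistributed. `generate_cohort()` therefore
simulates admissions whose *statistical structure* matches the
published study conditions, so every downstream stage is exercised on
realistic inputs:

* Stratum assignment: ACLF prevalence 54.0%, grade mix
  18.2% / 33.7% / 48.1% — the study's observed mix.
* Labs: each stratum's published median (Q1–Q3) is converted to a
  log-normal via `lognormal_from_median_iqr()` (`mu = ln median`,
  `sigma = (ln Q3 − ln Q1)/(2 z_{0.75})`); sodium and mean arterial
  pressure, approximately symmetric and bounded, use a truncated
  normal with `sd = IQR/1.349`. Labs are drawn independently within a
  stratum — no correlation structure is modelled.
* Organ failures are set *constructively*: the assigned grade fixes the
  number of failures (grade 3 draws 3–6 with decreasing probability),
  failed organs are chosen with weights reflecting the published
  failure mix, and the defining lab of each organ is re-drawn from the
  stratum log-normal *conditioned* on the correct side of the failure
  threshold. Conditioning (rather than clamping) avoids piling
  probability mass at the thresholds; pure rejection sampling was
  rejected because its runtime is unbounded for high-grade patients.
  Grade-1 patients with a non-kidney failure receive a creatinine in
  the 1.5–1.9 band so a grade-1 sub-rule holds. Ventilation is driven
  by respiratory failure; otherwise it is airway-protection-only, so it
  can never create an unintended respiratory failure. Every generated
  patient is verified to round-trip (`grade_aclf()` on the snapshot
  returns the assigned grade, 100% required) before outcomes are
  attached.
* Outcomes: 42-day mortality 8.4% (AD) and 22.5% / 34.2% / 63.8%
  (grades 1–3), converted to constant hazards by
  `hazard_from_mortality()` (`rate = −ln(1 − m)/horizon`). The study
  reports only 42-day totals, not within-window timing, so a constant
  hazard is an assumption, not an inference. Death times stay
  continuous to avoid mass ties in Kaplan–Meier and Cox computations;
  survivors are censored administratively at day 42.

**What the generator does and does not emulate.** It reproduces stratum
frequencies, stratum-conditional lab marginals (medians within the
pre-registered 20% tolerance for unconstrained labs and 35% for the
four labs re-drawn around failure thresholds, verified at n = 10,000),
organ-failure prevalences and grade-conditional mortality. It does
*not* reproduce: inter-lab correlations; any association between lab
values and hazard *within* a stratum (mortality depends on the stratum
only); AD patients with isolated organ failures (the generated AD
stratum has zero failures, a simplification of the published AD column
where a few isolated failures occur); longitudinal trajectories;
treatment effects or transplant competing risks. Consequently,
within-stratum discrimination (AUC) of the scores on synthetic data is
close to chance by construction, and passing tests demonstrate the
*correctness of the statistical machinery*, not the real-data
discrimination of the scores; reproducing the published AUCs would
require the original credentialed cohort.

## The validation suite

`run_pipeline()` chains the stages the study design prescribes:

* Baseline table: numeric variables are routed by a Kolmogorov–Smirnov
  normality check on the pooled sample (P > 0.05 → normal) to a
  pooled-variance t-test, otherwise to a Mann–Whitney test; categorical
  variables use the chi-square test without continuity correction. All
  tests two-sided at α = 0.05.
* Survival: Kaplan–Meier product-limit estimates (`km_estimate()`, via
  the `survival` package) and log-rank tests with k − 1 degrees of
  freedom (`log_rank()`).
* Cox proportional hazards (`cox_fit()`, Efron tie handling — with
  continuous simulated times ties never arise, but loaded data may
  have them): Wald 95% CIs and p-values; monotone likelihoods are
  flagged rather than silently reported. `backward_stepwise()` screens
  candidates univariately at α = 0.05, then removes the largest-p
  covariate (first listed on ties, making the procedure deterministic
  in the input order) until all retained p < α; an empty final model is
  a legitimate result, not an error. Covariates enter unscaled.
* Discrimination: `roc_auc()` is the Mann–Whitney estimator with
  midrank tie handling; higher score = higher risk, classification rule
  score ≥ cutoff. `youden_cutoff()` scans observed thresholds and
  breaks ties toward the smallest cutoff (maximizing sensitivity, the
  screening-oriented choice). DeLong variances/covariances and the
  paired AUC z-test come from `pROC`; a degenerate variance with a
  nonzero AUC difference is an error, while self- or rank-equivalent
  comparisons return p = 1 exactly.
* Calibration and overall performance: raw scores are not
  probabilities, and the source study does not state its transform, so
  Hosmer–Lemeshow, the calibration curve and the Brier score operate on
  probabilities from a univariable logistic recalibration
  (`score_to_risk()`) — the standard choice in the CLIF-consortium
  validation literature. Hosmer–Lemeshow uses equal-count risk bins
  (default 10; ties broken by input order; degenerate bins merged with
  a warning) and `groups − 2` degrees of freedom. R² is Nagelkerke's
  pseudo-R² from the null and fitted likelihoods — the study never
  defines its R², and Nagelkerke is the conventional reading alongside
  a Brier score.
* Stratum specificity: CLIF-C ACLF is evaluated only within the ACLF
  stratum and CLIF-C AD only within the AD stratum; the traditional
  scores are evaluated in both.

## Numerical and design choices

* Threshold comparisons are exact (`>=`, `>`) as written in the
  diagnostic definitions; kidney failure uses the strict `> 2`.
* `compute_meld_na()` clamps before subtracting, guaranteeing
  MELD-Na ≥ MELD.
* The Hosmer–Lemeshow statistic is exactly 0 whenever observed equals
  expected in every bin (tested on fixtures).
* Problem sizes in the test-suite simulations (1,500–12,000 patients,
  2,000 bootstrap replicates) are chosen so Monte-Carlo error is a
  small fraction of each asserted tolerance while the whole suite runs
  in well under a minute per file.
* Determinism: a `cohort_spec()` seed fixes the entire cohort;
  re-running any pipeline configuration reproduces byte-identical CSV
  and JSON outputs (tested).

## Known limitations

* Exponential within-stratum survival is an assumption forced by the
  available summaries; hazard shapes (early bleeding deaths vs late
  liver failure) are not modelled.
* The generated AD stratum contains no isolated organ failures, so the
  AD-stratum organ-failure prevalences are 0 rather than the small
  published percentages.
* The published SpO2/FiO2 summaries are extremely skewed with medians
  close to the physiological ceiling (~476); a two-parameter log-normal
  cannot match both the median and the ceiling, so the simulated AD
  oxygenation ratio runs lower than the published median (within the
  pre-registered tolerance for threshold-adjacent labs).
* No competing-risk handling for transplant (the study applied none;
  transplanted patients are a ~1.5% minority) and no multiple-testing
  correction across the univariate Cox screen (likewise by design).
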