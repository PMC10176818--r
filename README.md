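# avbaclf

Risk stratification of cirrhotic patients with acute variceal bleeding
(AVB) by acute-on-chronic liver failure (ACLF), with a full validation
toolkit for the competing prognostic scores.

## The problem

AVB is one of the deadliest decompensations of cirrhosis, yet its
6-week mortality varies enormously between patients. The EASL-CLIF
consortium defines ACLF as acute decompensation plus organ failure(s)
— liver, coagulation, kidney, circulation, respiration, brain — and
grades it 1–3 by the number of failing organs. The question this
package operationalizes: in ICU patients admitted for AVB, does the
ACLF diagnosis and grade stratify 6-week (42-day) mortality beyond the
traditional liver scores (CTP, MELD, MELD-Na), and how do the
CLIF-consortium scores (CLIF-C ACLF in the ACLF stratum, CLIF-C AD in
the acute-decompensation stratum) perform as continuous predictors?

The package provides:

* **Scores** — `compute_ctp()`, `compute_meld()`, `compute_meld_na()`,
  `compute_clif_of()`, `compute_clif_c_aclf()`, `compute_clif_c_ad()`,
  and `score_cohort()` to apply them all to a cohort data frame.
* **ACLF diagnosis** — `assess_organ_failures()` and `grade_aclf()`
  implementing the six EASL-CLIF organ-failure definitions and the
  grade 1/2/3 rules, including the single-failure sub-rules.
* **Synthetic cohort** — `cohort_spec()` + `generate_cohort()`, a
  seeded generator calibrated to published stratum frequencies, lab
  marginals and grade-conditional 42-day mortality, so the entire
  workflow runs without access to a credentialed clinical database.
* **Evaluation** — Kaplan–Meier estimates, log-rank tests, Cox models
  with backward stepwise selection, ROC/AUC with DeLong inference,
  Youden-optimal cutoffs, Hosmer–Lemeshow calibration, Brier score and
  Nagelkerke R² (`km_estimate()`, `log_rank()`, `cox_fit()`,
  `backward_stepwise()`, `roc_auc()`, `delong_test()`,
  `youden_cutoff()`, `score_performance()`, …).
* **Pipeline** — `run_pipeline()` / `write_report()` to run the whole
  analysis from a config and write deterministic CSV/JSON outputs.

See the vignette (`vignettes/aclf-risk-stratification.Rmd`) for the
statistical model, every diagnostic rule, the generator's design and
its stated limitations.

## Worked example

The `analysis/` directory holds the numbered study workflow. Running
it end to end (`Rscript analysis/01_simulate.R` … `05_performance.R`)
on the default seed produces, abridged:

```
simulated 335 admissions -> results/cohort.csv
ACLF prevalence: 51.9% (grades 1/2/3: 31/58/85)
42-day deaths: 96 (28.7%)

diagnostic round-trip agreement with assigned strata: 100%
median CTP/MELD/MELD-Na in ACLF: 11 / 30 / 32
baseline variables with p < 0.05 (AD vs ACLF): 21 of 23

  stratum   n survival_42d
       AD 161        91.3%
     ACLF 174        52.9%
   grade1  31        64.5%
   grade2  58        74.1%
   grade3  85        34.1%
log-rank AD vs ACLF: chi2 = 61.8, p = 3.85e-15
log-rank across grades (df 3): chi2 = 111.0, p = 6.52e-24

final multivariate model -> results/table2_cox_multivariate.csv
  has_aclf  HR 7.06 (95% CI 4.00-12.46), p = 1.49e-11

ACLF stratum (n = 174, 82 deaths):
  clif_c_aclf  AUC 0.573 (0.487-0.659)  J 0.16 at 65.35
AD stratum (n = 161, 14 deaths):
  clif_c_ad    AUC 0.623 (0.452-0.794)  J 0.27 at 55.15
```

Reading this: the generator produced a 335-patient cohort in which the
ACLF diagnosis recomputed from the simulated labs agrees with the
assigned stratum for every patient; ACLF patients are sicker on every
traditional score (median MELD 30 vs the AD stratum) and on 21 of 23
baseline variables. Survival separates sharply by stratum (91.3% vs
52.9% at 42 days) and by grade, and ACLF survives backward stepwise
Cox selection against 13 other admission covariates as the dominant
independent risk factor (HR ≈ 7 — larger than the hazard ratio a real
cohort would show, because the generator ties mortality to the stratum
alone). The grade-1 vs grade-2 inversion (64.5% vs 74.1%) is sampling
noise at n = 31/58. The within-stratum AUCs are near 0.5 *by
construction*: within a stratum the simulated labs are independent of
the hazard, so these numbers exercise the evaluation machinery rather
than reproduce real-data discrimination (see the vignette's
limitations section).

Single-patient use:

```r
library(avbaclf)
compute_meld(creatinine = 1.8, bilirubin = 4.2, inr = 1.9)
#> [1] 25

pt <- data.frame(bilirubin = 3.1, inr = 1.6, creatinine = 2.4,
                 on_rrt = FALSE, on_vasopressors = FALSE,
                 pao2_fio2 = NA, spo2_fio2 = 410, he_grade = 0,
                 on_mechanical_ventilation = FALSE,
                 mv_airway_protection_only = FALSE)
panel <- assess_organ_failures(pt)
grade_aclf(panel, creatinine = pt$creatinine, he_grade = pt$he_grade)
#>   has_aclf aclf_grade  rule_applied
#> 1     TRUE          1 single_kidney
```

## Reproduction

`scripts/acceptance.R` re-derives the headline quantities of the study
design from the installed package — stratified Kaplan–Meier survival
on a fixed reference cohort, grade-conditional mortality recovered
from large simulated cohorts, and the ACLF hazard ratio recovered by
Cox regression — and writes them to a JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seed controls every simulation in the script; rerunning with the
same seed reproduces the JSON byte for byte.
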