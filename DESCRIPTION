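Package: avbaclf
Title: ACLF-Based Risk Stratification for Cirrhotic Acute Variceal Bleeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical prognostic scoring and risk-stratification analysis for
    patients with cirrhosis hospitalized for acute variceal bleeding. Computes
    the Child-Turcotte-Pugh, MELD, MELD-Na, CLIF-OF, CLIF-C ACLF and CLIF-C AD
    scores from first-day clinical data, diagnoses and grades acute-on-chronic
    liver failure (ACLF) by the EASL-CLIF organ-failure rules, simulates
    seeded synthetic cohorts calibrated to published stratum-level lab
    distributions and 42-day mortality, and runs a full prognostic-validation
    pipeline: stratified baseline comparisons, Kaplan-Meier and log-rank
    survival analysis, univariate and backward-stepwise Cox proportional
    hazards regression, ROC discrimination with DeLong comparisons, Youden
    cutoffs, Hosmer-Lemeshow calibration and Brier/Nagelkerke overall
    performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
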