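#!/usr/bin/env Rscript
# Simulate the study cohort: 335 cirrhotic ICU admissions for acute
# variceal bleeding, 54% with ACLF (grade mix 18.2/33.7/48.1%), labs
# drawn from the published stratum medians/IQRs and 42-day survival
# from stratum-calibrated exponential hazards.

suppressPackageStartupMessages(library(avbaclf))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n = 335, seed = 1L)
cohort <- generate_cohort(spec)
write_cohort(cohort, "results/cohort.csv", spec)

cat(sprintf("simulated %d admissions -> results/cohort.csv\n", nrow(cohort)))
cat(sprintf("ACLF prevalence: %.1f%% (grades 1/2/3: %s)\n",
            100 * mean(cohort$group == "ACLF"),
            paste(table(cohort$aclf_grade_assigned[cohort$group == "ACLF"]),
                  collapse = "/")))
cat(sprintf("42-day deaths: %d (%.1f%%)\n", sum(cohort$event),
            100 * mean(cohort$event)))
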