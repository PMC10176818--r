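#!/usr/bin/env Rscript
# Univariate Cox screening of admission risk factors for 6-week
# mortality, followed by backward stepwise multivariate selection at
# alpha = 0.05; does ACLF remain an independent risk factor?

suppressPackageStartupMessages(library(avbaclf))

scored <- utils::read.csv("results/cohort_scored.csv")
scored$female <- as.integer(scored$sex == "female")
scored$any_ascites <- as.integer(scored$ascites_grade >= 1)
scored$has_aclf <- as.integer(scored$has_aclf)

candidates <- c("has_aclf", "age", "female", "any_ascites",
                "mean_arterial_pressure", "spo2_fio2", "wbc", "hemoglobin",
                "albumin", "bilirubin", "inr", "creatinine", "sodium",
                "potassium")
res <- backward_stepwise(scored, candidates, alpha = 0.05)

utils::write.csv(res$univariate, "results/table2_cox_univariate.csv",
                 row.names = FALSE)
cat("univariate Cox screen -> results/table2_cox_univariate.csv\n")
cat(sprintf("candidates passing screening at p < 0.05: %s\n",
            paste(res$univariate$term[res$univariate$p_value < 0.05],
                  collapse = ", ")))

if (is.null(res$final)) {
  cat("no covariate retained in the multivariate model\n")
} else {
  utils::write.csv(res$final$table, "results/table2_cox_multivariate.csv",
                   row.names = FALSE)
  cat("final multivariate model -> results/table2_cox_multivariate.csv\n")
  tab <- res$final$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                tab$term[i], tab$hazard_ratio[i], tab$ci_low[i],
                tab$ci_high[i], tab$p_value[i]))
}
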