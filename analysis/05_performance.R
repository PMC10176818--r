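#!/usr/bin/env Rscript
# Discrimination (AUC, DeLong CI, Youden cutoff), calibration
# (Hosmer-Lemeshow) and overall performance (Brier, Nagelkerke R2) of
# each prognostic score for 6-week mortality, computed separately in
# the ACLF stratum (CTP, MELD, MELD-Na, CLIF-C ACLF) and the AD stratum
# (CTP, MELD, MELD-Na, CLIF-C AD).

suppressPackageStartupMessages(library(avbaclf))

scored <- utils::read.csv("results/cohort_scored.csv")

for (stratum in c("ACLF", "AD")) {
  sub <- scored[scored$has_aclf == (stratum == "ACLF"), ]
  score_cols <- c(ctp = "ctp_points", meld = "meld", meld_na = "meld_na",
                  if (stratum == "ACLF") c(clif_c_aclf = "clif_c_aclf")
                  else c(clif_c_ad = "clif_c_ad"))
  tab <- do.call(rbind, lapply(names(score_cols), function(s) {
    sp <- score_performance(sub[[score_cols[[s]]]], sub$event)
    cbind(score = s, sp$summary)
  }))
  out <- sprintf("results/table3_performance_%s.csv", tolower(stratum))
  utils::write.csv(tab, out, row.names = FALSE)
  cat(sprintf("%s stratum (n = %d, %d deaths) -> %s\n",
              stratum, nrow(sub), sum(sub$event), out))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s AUC %.3f (%.3f-%.3f)  J %.2f at %.4g  Brier %.3f  R2 %.3f  HL p %.2f\n",
                tab$score[i], tab$auc[i], tab$auc_ci_low[i],
                tab$auc_ci_high[i], tab$youden_index[i], tab$cutoff[i],
                tab$brier[i], tab$r_squared[i], tab$hl_p[i]))
  # pairwise DeLong comparisons within the stratum
  combs <- utils::combn(names(score_cols), 2)
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    ok <- !is.na(sub[[score_cols[[a]]]]) & !is.na(sub[[score_cols[[b]]]])
    dl <- delong_test(sub[[score_cols[[a]]]][ok],
                      sub[[score_cols[[b]]]][ok], sub$event[ok])
    cat(sprintf("  DeLong %s vs %s: p = %.2f\n", a, b, dl$p_value))
  }
}
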