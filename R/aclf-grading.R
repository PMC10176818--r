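#' Assess EASL-CLIF organ failures
#'
#' Applies the six organ-failure definitions to first-day data:
#' liver, total bilirubin >= 12 mg/dL; coagulation, INR >= 2.5; kidney,
#' creatinine > 2 mg/dL or renal replacement therapy; circulation,
#' vasopressor requirement; respiration, PaO2/FiO2 <= 200 (SpO2/FiO2
#' <= 214 when PaO2/FiO2 is unavailable) or mechanical ventilation for
#' reasons other than airway protection in the absence of HE grade
#' III--IV; brain, HE grade III--IV (West Haven).
#'
#' A missing oxygenation ratio is treated as not failed by that
#' criterion alone.
#'
#' @param cohort A cohort data frame in the schema of [cohort_schema()]
#'   (only the organ-system columns are used).
#' @return A data frame of logical columns `fail_liver`,
#'   `fail_coagulation`, `fail_kidney`, `fail_circulation`,
#'   `fail_respiration`, `fail_brain` and integer `n_failures` (0--6).
#' @export
assess_organ_failures <- function(cohort) {
  ratio_fail <- ifelse(!is.na(cohort$pao2_fio2), cohort$pao2_fio2 <= 200,
                       !is.na(cohort$spo2_fio2) & cohort$spo2_fio2 <= 214)
  mv_fail <- as.logical(cohort$on_mechanical_ventilation) &
    !as.logical(cohort$mv_airway_protection_only) & cohort$he_grade < 3
  panel <- data.frame(
    fail_liver = cohort$bilirubin >= 12,
    fail_coagulation = cohort$inr >= 2.5,
    fail_kidney = cohort$creatinine > 2 | as.logical(cohort$on_rrt),
    fail_circulation = as.logical(cohort$on_vasopressors),
    fail_respiration = ratio_fail | mv_fail,
    fail_brain = cohort$he_grade >= 3
  )
  panel$n_failures <- as.integer(rowSums(panel))
  panel
}

#' Diagnose and grade ACLF
#'
#' EASL-CLIF grading from an organ-failure panel. Three or more organ
#' failures give grade 3 and exactly two give grade 2. A single failure
#' gives grade 1 only when one of three sub-rules matches: (1) the single
#' failure is the kidney; (2) a single liver, coagulation, circulation or
#' respiration failure is accompanied by serum creatinine 1.5--1.9 mg/dL
#' and/or HE grade I--II; (3) a single brain failure is accompanied by
#' serum creatinine 1.5--1.9 mg/dL. Otherwise the patient is classed as
#' acute decompensation without ACLF (grade 0).
#'
#' The creatinine band is taken as [1.5, 2.0) intersected with the
#' absence of kidney failure, so it can never promote a patient whose
#' creatinine already meets the kidney-failure criterion.
#'
#' @param panel Organ-failure panel from [assess_organ_failures()].
#' @param creatinine Serum creatinine, mg/dL (same order as `panel`).
#' @param he_grade West Haven HE grade, 0--4.
#' @return A data frame with `has_aclf` (logical), `aclf_grade`
#'   (integer 0--3; 0 = AD) and `rule_applied` (character: one of
#'   `none`, `single_kidney`, `single_other_with_cr_or_he`,
#'   `single_brain_with_cr`, `two_failures`, `three_plus_failures`).
#' @export
grade_aclf <- function(panel, creatinine, he_grade) {
  needed <- c("fail_liver", "fail_coagulation", "fail_kidney",
              "fail_circulation", "fail_respiration", "fail_brain",
              "n_failures")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0L)
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         "; use assess_organ_failures() to build it", call. = FALSE)
  stopifnot(nrow(panel) == length(creatinine),
            length(creatinine) == length(he_grade))
  n_fail <- panel$n_failures
  cr_band <- creatinine >= 1.5 & creatinine < 2.0
  he_mild <- he_grade %in% 1:2

  single_kidney <- n_fail == 1L & panel$fail_kidney
  single_other <- n_fail == 1L &
    (panel$fail_liver | panel$fail_coagulation |
       panel$fail_circulation | panel$fail_respiration) &
    (cr_band | he_mild)
  single_brain <- n_fail == 1L & panel$fail_brain & cr_band

  grade <- integer(nrow(panel))
  grade[single_kidney | single_other | single_brain] <- 1L
  grade[n_fail == 2L] <- 2L
  grade[n_fail >= 3L] <- 3L

  rule <- rep("none", nrow(panel))
  rule[single_brain] <- "single_brain_with_cr"
  rule[single_other] <- "single_other_with_cr_or_he"
  rule[single_kidney] <- "single_kidney"
  rule[n_fail == 2L] <- "two_failures"
  rule[n_fail >= 3L] <- "three_plus_failures"

  data.frame(has_aclf = grade >= 1L, aclf_grade = grade,
             rule_applied = rule)
}
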