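#' Child-Turcotte-Pugh score
#'
#' Computes the CTP score from its five components using the INR-based
#' variant of the component table: bilirubin (<2 / 2--3 / >3 mg/dL),
#' albumin (>3.5 / 2.8--3.5 / <2.8 g/dL), INR (<1.7 / 1.7--2.3 / >2.3),
#' ascites (none / mild / moderate-severe) and hepatic encephalopathy
#' (none / grade I--II / grade III--IV), each scored 1--3 points.
#'
#' @param bilirubin Total serum bilirubin, mg/dL.
#' @param albumin Serum albumin, g/dL.
#' @param inr International normalized ratio.
#' @param ascites_grade Ordinal 0 (none), 1 (mild), 2 (moderate/severe).
#' @param he_grade West Haven hepatic encephalopathy grade, integer 0--4.
#'
#' @return A data frame with columns `ctp_points` (integer, 5--15) and
#'   `ctp_class` (factor with levels A, B, C; A: 5--6, B: 7--9, C: 10--15).
#'
#' @examples
#' compute_ctp(2.5, 2.9, 1.8, ascites_grade = 1, he_grade = 1)
#' @export
compute_ctp <- function(bilirubin, albumin, inr, ascites_grade, he_grade) {
  check_required(bilirubin = bilirubin, albumin = albumin, inr = inr,
                 ascites_grade = ascites_grade, he_grade = he_grade)
  stopifnot(all(ascites_grade %in% 0:2), all(he_grade %in% 0:4))
  bili_pts <- 1L + (bilirubin >= 2) + (bilirubin > 3)
  alb_pts  <- 1L + (albumin <= 3.5) + (albumin < 2.8)
  inr_pts  <- 1L + (inr >= 1.7) + (inr > 2.3)
  asc_pts  <- 1L + (ascites_grade >= 1) + (ascites_grade >= 2)
  he_pts   <- 1L + (he_grade >= 1) + (he_grade >= 3)
  pts <- as.integer(bili_pts + alb_pts + inr_pts + asc_pts + he_pts)
  cls <- cut(pts, breaks = c(4, 6, 9, 15), labels = c("A", "B", "C"))
  data.frame(ctp_points = pts, ctp_class = cls)
}

#' MELD score (UNOS formula)
#'
#' Classic (pre-2016) MELD: 9.57 ln(creatinine) + 3.78 ln(bilirubin) +
#' 11.2 ln(INR) + 6.43, with creatinine, bilirubin and INR floored at 1.0,
#' creatinine capped at 4.0, creatinine set to 4.0 for patients on renal
#' replacement therapy, and the total rounded to the nearest integer.
#'
#' @param creatinine Serum creatinine, mg/dL.
#' @param bilirubin Total serum bilirubin, mg/dL.
#' @param inr International normalized ratio.
#' @param on_rrt Logical; on renal replacement therapy.
#' @param meld_precomputed Optional externally supplied MELD; where
#'   non-missing it takes precedence over the formula.
#'
#' @return Integer MELD points (minimum 6).
#' @examples
#' compute_meld(2.0, 4.0, 2.0)  # 26
#' @export
compute_meld <- function(creatinine, bilirubin, inr, on_rrt = FALSE,
                         meld_precomputed = NULL) {
  check_required(creatinine = creatinine, bilirubin = bilirubin, inr = inr)
  if (any(creatinine <= 0 | bilirubin <= 0 | inr <= 0))
    stop("creatinine, bilirubin and inr must be strictly positive")
  cr <- pmin(pmax(creatinine, 1), 4)
  cr[as.logical(on_rrt)] <- 4
  bi <- pmax(bilirubin, 1)
  ir <- pmax(inr, 1)
  meld <- as.integer(round(9.57 * log(cr) + 3.78 * log(bi) +
                             11.2 * log(ir) + 6.43))
  if (!is.null(meld_precomputed)) {
    keep <- !is.na(meld_precomputed)
    meld[keep] <- as.integer(meld_precomputed[keep])
  }
  meld
}

#' MELD-Na score
#'
#' MELD-Na = MELD + 1.59 (135 - Na), with sodium clamped into
#' [120, 135] mEq/L so the correction is never negative.
#'
#' @param meld MELD points.
#' @param sodium Serum sodium, mEq/L.
#' @return MELD-Na points (numeric; always >= `meld`).
#' @examples
#' compute_meld_na(20, 130)  # 27.95
#' @export
compute_meld_na <- function(meld, sodium) {
  check_required(meld = meld, sodium = sodium)
  if (any(sodium <= 0)) stop("sodium must be strictly positive")
  na <- pmin(pmax(sodium, 120), 135)
  meld + 1.59 * (135 - na)
}

#' CLIF-OF organ-failure score
#'
#' Scores six organ systems 1--3 and sums them (range 6--18). Except for
#' the kidney, the subscore-3 thresholds coincide with the EASL-CLIF
#' organ-failure definitions used by [assess_organ_failures()]; kidney
#' failure (creatinine > 2 mg/dL or RRT) starts inside subscore 2 of the
#' published kidney row, as in the original CLIF-OF scale. Boundaries:
#' liver bilirubin <6 / 6--<12 / >=12 mg/dL; kidney creatinine <2 /
#' 2--<3.5 / >=3.5 mg/dL or RRT; brain HE grade 0 / I--II / III--IV;
#' coagulation INR <2.0 / 2.0--<2.5 / >=2.5; circulation MAP >=70 /
#' <70 mmHg / on vasopressors; respiration PaO2/FiO2 >300 / 201--300 /
#' <=200 (SpO2/FiO2 >357 / 215--357 / <=214 when PaO2/FiO2 is missing).
#' Mechanical ventilation for reasons other than airway protection, in
#' the absence of HE grade III--IV, also scores respiration 3.
#'
#' @param bilirubin Total bilirubin, mg/dL.
#' @param creatinine Serum creatinine, mg/dL.
#' @param he_grade West Haven HE grade, 0--4.
#' @param inr International normalized ratio.
#' @param map Mean arterial pressure, mmHg.
#' @param on_vasopressors Logical.
#' @param on_rrt Logical.
#' @param pao2_fio2,spo2_fio2 Oxygenation ratios; at least one per patient.
#'   PaO2/FiO2 is preferred when both are present.
#' @param on_mechanical_ventilation,mv_airway_protection_only Logical flags
#'   for the respiratory ventilation criterion.
#'
#' @return A data frame with `clif_of` (total, 6--18) and the six
#'   subscores `of_liver`, `of_kidney`, `of_brain`, `of_coagulation`,
#'   `of_circulation`, `of_respiration` (each 1--3).
#' @export
compute_clif_of <- function(bilirubin, creatinine, he_grade, inr, map,
                            on_vasopressors, on_rrt,
                            pao2_fio2 = NA_real_, spo2_fio2 = NA_real_,
                            on_mechanical_ventilation = FALSE,
                            mv_airway_protection_only = FALSE) {
  check_required(bilirubin = bilirubin, creatinine = creatinine,
                 he_grade = he_grade, inr = inr, map = map,
                 on_vasopressors = on_vasopressors, on_rrt = on_rrt)
  n <- length(bilirubin)
  pao2_fio2 <- rep_len(pao2_fio2, n)
  spo2_fio2 <- rep_len(spo2_fio2, n)
  if (any(is.na(pao2_fio2) & is.na(spo2_fio2)))
    stop("missing field: at least one of pao2_fio2/spo2_fio2 is required")
  on_mv <- rep_len(as.logical(on_mechanical_ventilation), n)
  mv_ap <- rep_len(as.logical(mv_airway_protection_only), n)

  liver  <- 1L + (bilirubin >= 6) + (bilirubin >= 12)
  kidney <- pmax(1L + (creatinine >= 2) + (creatinine >= 3.5),
                 ifelse(as.logical(on_rrt), 3L, 1L))
  brain  <- 1L + (he_grade >= 1) + (he_grade >= 3)
  coag   <- 1L + (inr >= 2.0) + (inr >= 2.5)
  circ   <- ifelse(as.logical(on_vasopressors), 3L, 1L + (map < 70))
  resp_ratio <- ifelse(!is.na(pao2_fio2),
                       1L + (pao2_fio2 <= 300) + (pao2_fio2 <= 200),
                       1L + (spo2_fio2 <= 357) + (spo2_fio2 <= 214))
  mv_failure <- on_mv & !mv_ap & he_grade < 3
  resp <- pmax(resp_ratio, ifelse(mv_failure, 3L, 1L))

  sub <- data.frame(of_liver = as.integer(liver),
                    of_kidney = as.integer(kidney),
                    of_brain = as.integer(brain),
                    of_coagulation = as.integer(coag),
                    of_circulation = as.integer(circ),
                    of_respiration = as.integer(resp))
  cbind(clif_of = as.integer(rowSums(sub)), sub)
}

#' CLIF-C ACLF prognostic score
#'
#' CLIF-C ACLF = 10 x (0.33 x CLIF-OF + 0.04 x age + 0.63 x ln(WBC) - 2).
#' Defined only for patients with ACLF; strictly increasing in each
#' argument. No rounding is applied.
#'
#' @param clif_of CLIF-OF total score, 6--18.
#' @param age Age in years (>= 18).
#' @param wbc White blood cell count, 10^9 cells/L.
#' @return Numeric score.
#' @examples
#' compute_clif_c_aclf(9, 55, 13.9)
#' @export
compute_clif_c_aclf <- function(clif_of, age, wbc) {
  check_required(clif_of = clif_of, age = age, wbc = wbc)
  if (any(wbc <= 0)) stop("wbc must be strictly positive")
  stopifnot(all(clif_of >= 6 & clif_of <= 18), all(age >= 18))
  10 * (0.33 * clif_of + 0.04 * age + 0.63 * log(wbc) - 2)
}

#' CLIF-C AD prognostic score
#'
#' CLIF-C AD = 10 x (0.03 x age + 0.66 x ln(creatinine) + 1.71 x ln(INR)
#' + 0.88 x ln(WBC) - 0.05 x sodium + 8). Defined only for acutely
#' decompensated patients without ACLF; increasing in age, creatinine,
#' INR and WBC and decreasing in sodium. No rounding is applied.
#'
#' @param age Age in years (>= 18).
#' @param creatinine Serum creatinine, mg/dL.
#' @param inr International normalized ratio.
#' @param wbc White blood cell count, 10^9 cells/L.
#' @param sodium Serum sodium, mmol/L.
#' @return Numeric score.
#' @examples
#' compute_clif_c_ad(55, 0.8, 1.6, 7.7, 138)
#' @export
compute_clif_c_ad <- function(age, creatinine, inr, wbc, sodium) {
  check_required(age = age, creatinine = creatinine, inr = inr,
                 wbc = wbc, sodium = sodium)
  if (any(creatinine <= 0 | inr <= 0 | wbc <= 0 | sodium <= 0))
    stop("all inputs must be strictly positive")
  stopifnot(all(age >= 18))
  10 * (0.03 * age + 0.66 * log(creatinine) + 1.71 * log(inr) +
          0.88 * log(wbc) - 0.05 * sodium + 8)
}

#' Compute all prognostic scores for a cohort
#'
#' Applies [compute_ctp()], [compute_meld()], [compute_meld_na()],
#' [compute_clif_of()], [assess_organ_failures()] and [grade_aclf()]
#' row-wise to a cohort data frame, then computes CLIF-C ACLF for
#' patients with ACLF and CLIF-C AD for patients without (each score is
#' `NA` in the stratum where it is not defined).
#'
#' @param cohort A cohort data frame in the schema of [cohort_schema()].
#' @return The cohort with score, organ-failure and grading columns
#'   appended: `ctp_points`, `ctp_class`, `meld`, `meld_na`, `clif_of`,
#'   the six `of_*` subscores, the six `fail_*` flags, `n_failures`,
#'   `has_aclf`, `aclf_grade`, `clif_c_aclf`, `clif_c_ad`.
#' @export
score_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ctp <- compute_ctp(cohort$bilirubin, cohort$albumin, cohort$inr,
                     cohort$ascites_grade, cohort$he_grade)
  meld <- compute_meld(cohort$creatinine, cohort$bilirubin, cohort$inr,
                       cohort$on_rrt, cohort$meld_precomputed)
  of <- compute_clif_of(cohort$bilirubin, cohort$creatinine, cohort$he_grade,
                        cohort$inr, cohort$mean_arterial_pressure,
                        cohort$on_vasopressors, cohort$on_rrt,
                        cohort$pao2_fio2, cohort$spo2_fio2,
                        cohort$on_mechanical_ventilation,
                        cohort$mv_airway_protection_only)
  panel <- assess_organ_failures(cohort)
  aclf <- grade_aclf(panel, cohort$creatinine, cohort$he_grade)
  out <- cbind(cohort, ctp,
               data.frame(meld = meld,
                          meld_na = compute_meld_na(meld, cohort$sodium)),
               of, panel, aclf)
  out$clif_c_aclf <- ifelse(out$has_aclf,
                            compute_clif_c_aclf(out$clif_of, out$age, out$wbc),
                            NA_real_)
  out$clif_c_ad <- ifelse(!out$has_aclf,
                          compute_clif_c_ad(out$age, out$creatinine, out$inr,
                                            out$wbc, out$sodium),
                          NA_real_)
  out
}

# error with the offending field's name when a required input is missing
check_required <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || any(is.na(args[[nm]])))
      stop(sprintf("missing field: %s", nm), call. = FALSE)
  }
  invisible(TRUE)
}
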