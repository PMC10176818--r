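#' Cohort CSV schema
#'
#' Column names, types and units of the one-row-per-admission cohort
#' table consumed by [score_cohort()] and the evaluation pipeline.
#' Hepatic encephalopathy is encoded as the West Haven grade 0--4,
#' ascites as 0 (none) / 1 (mild) / 2 (moderate or severe), flags as
#' 0/1, and missing optional oxygenation ratios as empty cells.
#'
#' @return A data frame with columns `column`, `type`, `units`, `required`.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("patient_id", "age", "sex", "bilirubin", "albumin", "inr",
               "creatinine", "sodium", "potassium", "wbc", "hemoglobin",
               "mean_arterial_pressure", "pao2_fio2", "spo2_fio2",
               "he_grade", "ascites_grade", "on_vasopressors",
               "on_mechanical_ventilation", "mv_airway_protection_only",
               "on_rrt", "meld_precomputed", "time", "event"),
    type = c("character", "numeric", "character", rep("numeric", 9),
             "numeric", "numeric", "integer", "integer",
             rep("flag", 4), "numeric", "numeric", "flag"),
    units = c("", "years", "male/female", "mg/dL", "g/dL", "", "mg/dL",
              "mEq/L", "mEq/L", "10^9/L", "g/dL", "mmHg", "", "",
              "West Haven 0-4", "0-2", "", "", "", "", "points", "days",
              "1=death"),
    required = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Validate a cohort data frame
#'
#' Checks presence of required columns, strict positivity of labs, the
#' adult age floor, availability of at least one oxygenation ratio per
#' patient, and that airway-protection-only ventilation implies
#' ventilation. Violations are reported with row and column context.
#'
#' @param cohort Data frame to check.
#' @return The cohort, invisibly, on success.
#' @export
validate_cohort <- function(cohort) {
  sch <- cohort_schema()
  need <- setdiff(sch$column[sch$required], names(cohort))
  if (length(need) > 0)
    stop("cohort is missing required columns: ", paste(need, collapse = ", "))
  for (opt in setdiff(sch$column, names(cohort)))
    cohort[[opt]] <- NA
  bad_row <- function(ok, what) {
    if (!all(ok, na.rm = FALSE)) {
      i <- which(!ok | is.na(ok))[1]
      stop(sprintf("cohort row %d: %s", i, what), call. = FALSE)
    }
  }
  bad_row(cohort$age >= 18, "age must be >= 18")
  for (lab in c("bilirubin", "albumin", "inr", "creatinine", "sodium", "wbc"))
    bad_row(cohort[[lab]] > 0,
            sprintf("column %s must be strictly positive", lab))
  bad_row(!is.na(cohort$pao2_fio2) | !is.na(cohort$spo2_fio2),
          "at least one of pao2_fio2/spo2_fio2 must be present")
  bad_row(!(as.logical(cohort$mv_airway_protection_only) &
              !as.logical(cohort$on_mechanical_ventilation)),
          "mv_airway_protection_only requires on_mechanical_ventilation")
  bad_row(cohort$he_grade %in% 0:4, "he_grade must be in 0..4")
  bad_row(cohort$ascites_grade %in% 0:2, "ascites_grade must be in 0..2")
  invisible(cohort)
}

#' Write a cohort CSV with a JSON sidecar
#'
#' Writes the cohort in the [cohort_schema()] layout and, when a
#' [cohort_spec()] is supplied, a `<path>.json` sidecar echoing the full
#' generator specification and seed so a run can be reproduced exactly.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @param spec Optional [cohort_spec()] used to generate the cohort.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' @param path CSV path in the [cohort_schema()] layout.
#' @return Validated cohort data frame; flag columns coerced to logical.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in c("on_vasopressors", "on_mechanical_ventilation",
               "mv_airway_protection_only", "on_rrt", "event")) {
    if (fl %in% names(cohort)) cohort[[fl]] <- as.logical(cohort[[fl]])
  }
  validate_cohort(cohort)
  cohort
}
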