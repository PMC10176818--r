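#' Pipeline run configuration
#'
#' @param mode "simulate" (use `spec`) or "load" (use `input`).
#' @param spec A [cohort_spec()] (simulate mode).
#' @param input Path to a cohort CSV (load mode).
#' @param horizon Outcome horizon in days (default 42, the 6-week
#'   mortality endpoint).
#' @param out Optional output directory for report tables.
#' @param seed Integer seed; in simulate mode it overrides `spec$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), spec = NULL,
                       input = NULL, horizon = 42, out = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(spec)) spec <- cohort_spec(seed = seed)
  if (mode == "simulate") spec$seed <- as.integer(seed)
  if (mode == "load" && is.null(input)) stop("load mode requires `input`")
  if (!is.null(spec) && !is.null(input))
    stop("exactly one of `spec` and `input` must be given")
  stopifnot(horizon > 0)
  structure(list(mode = mode, spec = spec, input = input, horizon = horizon,
                 out = out, seed = as.integer(seed)), class = "run_config")
}

# variables entering the baseline comparison and the Cox screen
.numeric_baseline <- c("age", "wbc", "hemoglobin", "bilirubin", "albumin",
                       "inr", "creatinine", "sodium", "potassium",
                       "mean_arterial_pressure", "spo2_fio2",
                       "ctp_points", "meld", "meld_na")
.cox_candidates <- c("has_aclf", "age", "female", "any_ascites",
                     "mean_arterial_pressure", "spo2_fio2", "wbc",
                     "hemoglobin", "albumin", "bilirubin", "inr",
                     "creatinine", "sodium", "potassium")

#' Baseline characteristics table, AD versus ACLF
#'
#' Compares each first-day variable between the AD and ACLF strata with
#' the distribution-routed test of [group_compare()]: numeric variables
#' via KS-routed t-test / Mann-Whitney, categorical via chi-square.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @return Data frame: variable, summaries per stratum, test, p_value.
#' @export
baseline_table <- function(scored) {
  ad <- scored[!scored$has_aclf, ]
  aclf <- scored[scored$has_aclf, ]
  summ <- function(x) sprintf("%.1f (%.1f-%.1f)",
                              stats::median(x, na.rm = TRUE),
                              stats::quantile(x, 0.25, na.rm = TRUE),
                              stats::quantile(x, 0.75, na.rm = TRUE))
  num <- do.call(rbind, lapply(.numeric_baseline, function(v) {
    gc <- group_compare(ad[[v]], aclf[[v]])
    data.frame(variable = v, ad = summ(ad[[v]]), aclf = summ(aclf[[v]]),
               test = gc$test, p_value = gc$p_value)
  }))
  cat_vars <- c("on_vasopressors", "on_mechanical_ventilation", "on_rrt",
                "fail_liver", "fail_coagulation", "fail_kidney",
                "fail_circulation", "fail_respiration", "fail_brain")
  cats <- do.call(rbind, lapply(cat_vars, function(v) {
    tab <- rbind(table(factor(ad[[v]], c(FALSE, TRUE))),
                 table(factor(aclf[[v]], c(FALSE, TRUE))))
    gc <- tryCatch(group_compare(tab),
                   error = function(e) list(test = "chi-square",
                                            p_value = NA_real_))
    pct <- function(x) sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
    data.frame(variable = v, ad = pct(ad[[v]]), aclf = pct(aclf[[v]]),
               test = gc$test, p_value = gc$p_value)
  }))
  rbind(num, cats)
}

#' Run the full risk-stratification analysis
#'
#' Simulates or loads a cohort, computes all prognostic scores, grades
#' ACLF, and produces the report bundle: a baseline table stratified AD
#' versus ACLF, Kaplan-Meier survival with log-rank tests by stratum and
#' by ACLF grade, univariate plus backward-stepwise multivariate Cox
#' regression for the 6-week mortality endpoint, and a per-score
#' performance table computed separately within the ACLF stratum (CTP,
#' MELD, MELD-Na, CLIF-C ACLF) and the AD stratum (CTP, MELD, MELD-Na,
#' CLIF-C AD), honoring the score-to-stratum specificity of the CLIF-C
#' scores. All outputs are deterministic given the configuration seed.
#'
#' With no events at the horizon the survival/Cox/performance stages are
#' skipped with a warning; scoring and grading are still returned.
#'
#' @param config A [run_config()].
#' @return A list of class `aclf_report` with elements `cohort` (scored),
#'   `baseline`, `survival` (KM at horizon per stratum and grade plus
#'   log-rank results), `cox` (univariate table and stepwise final
#'   model), `performance` (per-stratum score performance tables) and
#'   `config`. When `config$out` is set, each table is also written as
#'   CSV together with a JSON metrics bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (config$mode == "simulate") generate_cohort(config$spec)
            else read_cohort(config$input)
  scored <- score_cohort(cohort)
  horizon <- config$horizon
  scored$event42 <- as.integer(scored$event == 1 & scored$time <= horizon)

  report <- list(cohort = scored, baseline = baseline_table(scored),
                 config = config)

  if (sum(scored$event42, na.rm = TRUE) == 0) {
    warning("no events before the horizon: survival, Cox and performance stages skipped")
    report$survival <- report$cox <- report$performance <- NULL
    class(report) <- "aclf_report"
    if (!is.null(config$out)) write_report(report)
    return(report)
  }

  grp <- ifelse(scored$has_aclf, "ACLF", "AD")
  km_by <- function(idx) km_estimate(scored$time[idx], scored$event[idx],
                                     horizon)
  surv <- list(
    km = data.frame(
      stratum = c("AD", "ACLF", paste0("grade", 1:3)),
      n = c(sum(grp == "AD"), sum(grp == "ACLF"),
            vapply(1:3, function(g) sum(scored$aclf_grade == g), numeric(1))),
      survival_at_horizon = c(
        km_by(grp == "AD"), km_by(grp == "ACLF"),
        vapply(1:3, function(g) km_by(scored$aclf_grade == g), numeric(1)))),
    logrank_ad_vs_aclf = log_rank(scored$time, scored$event, grp),
    logrank_by_grade = log_rank(scored$time, scored$event,
                                scored$aclf_grade))

  cx <- scored
  cx$female <- as.integer(cx$sex == "female")
  cx$any_ascites <- as.integer(cx$ascites_grade >= 1)
  cx$has_aclf <- as.integer(cx$has_aclf)
  cand <- intersect(.cox_candidates,
                    names(cx)[vapply(cx, function(x)
                      is.numeric(x) && length(unique(x)) > 1, logical(1))])
  cox <- backward_stepwise(cx, cand, alpha = 0.05)

  perf <- list()
  for (stratum in c("ACLF", "AD")) {
    sub <- scored[grp == stratum, ]
    if (sum(sub$event42) == 0 || all(sub$event42 == 1)) {
      warning(sprintf("stratum %s skipped: outcome is single-class", stratum))
      next
    }
    score_cols <- c(ctp = "ctp_points", meld = "meld", meld_na = "meld_na",
                    if (stratum == "ACLF") c(clif_c_aclf = "clif_c_aclf")
                    else c(clif_c_ad = "clif_c_ad"))
    perf[[stratum]] <- do.call(rbind, lapply(names(score_cols), function(s) {
      sp <- score_performance(sub[[score_cols[[s]]]], sub$event42)
      cbind(score = s, sp$summary)
    }))
  }

  report$survival <- surv
  report$cox <- cox
  report$performance <- perf
  class(report) <- "aclf_report"
  if (!is.null(config$out)) write_report(report)
  report
}

#' Write an analysis report bundle to disk
#'
#' Emits the baseline, survival, Cox and performance tables as CSV files
#' plus a machine-readable JSON metrics bundle under the configured
#' output directory. Re-running with the same configuration and seed
#' reproduces byte-identical files.
#'
#' @param report An `aclf_report` from [run_pipeline()].
#' @return The output directory, invisibly.
#' @export
write_report <- function(report) {
  out <- report$config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  wr(report$cohort, "cohort_scored.csv")
  wr(report$baseline, "table1_baseline.csv")
  metrics <- list(seed = report$config$seed, horizon = report$config$horizon)
  if (!is.null(report$survival)) {
    wr(report$survival$km, "fig1_km_at_horizon.csv")
    metrics$logrank_ad_vs_aclf_p <- report$survival$logrank_ad_vs_aclf$p_value
    metrics$logrank_by_grade_p <- report$survival$logrank_by_grade$p_value
    metrics$km <- report$survival$km
  }
  if (!is.null(report$cox)) {
    wr(report$cox$univariate, "table2_cox_univariate.csv")
    if (!is.null(report$cox$final))
      wr(report$cox$final$table, "table2_cox_multivariate.csv")
  }
  if (length(report$performance) > 0) {
    for (s in names(report$performance))
      wr(report$performance[[s]],
         sprintf("table3_performance_%s.csv", tolower(s)))
    metrics$performance <- report$performance
  }
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
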