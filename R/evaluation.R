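#' Distribution-routed two-group comparison
#'
#' Reproduces the routing used for baseline tables in clinical studies:
#' numeric variables are tested for normality with a Kolmogorov-Smirnov
#' test on the pooled sample (against a normal with the pooled mean and
#' SD; P > 0.05 taken as normal) and compared with an independent-sample
#' t-test when normal or a Mann-Whitney test when skewed; categorical
#' variables, supplied as a contingency table, are compared with a
#' chi-square test. All p-values are two-sided.
#'
#' @param a,b Numeric vectors (one per group), or `a` a matrix/table of
#'   counts with groups in rows (then `b` is ignored).
#' @return A list with `test` ("t-test", "mann-whitney" or "chi-square"),
#'   `statistic` and `p_value`.
#' @export
group_compare <- function(a, b = NULL) {
  if (is.matrix(a) || is.table(a)) {
    ht <- suppressWarnings(stats::chisq.test(a, correct = FALSE))
    return(list(test = "chi-square", statistic = unname(ht$statistic),
                p_value = ht$p.value))
  }
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations")
  pooled <- c(a, b)
  ks <- suppressWarnings(
    stats::ks.test(pooled, "pnorm", mean(pooled), stats::sd(pooled)))
  if (ks$p.value > 0.05) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(test = "t-test", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
}

#' Kaplan-Meier survival probability at a time point
#'
#' Product-limit estimate of S(t). With no censoring before `at` this
#' equals 1 - d/n.
#'
#' @param time Follow-up times (days), > 0.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param at Time at which to evaluate the survival probability.
#' @return Survival probability in [0, 1].
#' @export
km_estimate <- function(time, event, at) {
  if (length(time) == 0) stop("empty survival input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  summary(fit, times = at, extend = TRUE)$surv
}

#' Log-rank test for k survival curves
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom.
#'
#' @param time,event Follow-up times and death indicators.
#' @param group Group labels (2 or more levels).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
log_rank <- function(time, event, group) {
  if (sum(event) == 0) stop("log-rank undefined: no events in any group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Efron handling of ties and
#' returns per-covariate hazard ratios with Wald 95% confidence
#' intervals and p-values. A monotone likelihood (perfect separation)
#' yields a convergence warning and the affected coefficient is flagged.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @return A list of class `cox_result` with elements `table` (data frame:
#'   term, coef, hazard_ratio, ci_low, ci_high, p_value, flagged),
#'   `loglik` (log partial likelihood at the optimum), `covariates` and
#'   `model` (the underlying `coxph` fit).
#' @export
cox_fit <- function(data, covariates) {
  if (sum(data$event) < 1) stop("at least one event is required")
  for (cv in covariates)
    if (length(unique(data[[cv]])) < 2)
      stop(sprintf("covariate %s is constant (non-identifiable)", cv))
  fm <- stats::reformulate(covariates,
                           response = "survival::Surv(time, event)")
  flagged_any <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fm, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w))) {
        flagged_any <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hazard_ratio = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - stats::qnorm(0.975) * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + stats::qnorm(0.975) * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    flagged = flagged_any | abs(co[, "coef"]) > 15,
    row.names = NULL)
  if (any(tab$flagged))
    warning("possible monotone likelihood: coefficient flagged")
  structure(list(table = tab, loglik = fit$loglik[2],
                 covariates = covariates, model = fit),
            class = "cox_result")
}

#' Backward stepwise Cox selection
#'
#' Screens candidates by univariate Cox fits at `alpha`, then fits the
#' multivariate model on the survivors and iteratively removes the
#' covariate with the largest Wald p-value until every retained
#' covariate has p < `alpha`. Deterministic given the input order: when
#' p-values tie, the covariate listed first is removed.
#'
#' @param data Data frame with `time`, `event` and candidate columns.
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Retention significance level (default 0.05).
#' @return A list with `univariate` (data frame of all candidate
#'   univariate fits), `final` (a `cox_result`, or NULL when no
#'   candidate passes screening) and `removed` (covariates dropped
#'   during backward elimination, in order).
#' @export
backward_stepwise <- function(data, candidates, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  uni <- do.call(rbind, lapply(candidates, function(cv) {
    tab <- cox_fit(data, cv)$table
    tab$term <- cv
    tab
  }))
  keep <- uni$term[uni$p_value < alpha]
  if (length(keep) == 0)
    return(list(univariate = uni, final = NULL, removed = character()))
  removed <- character()
  repeat {
    fit <- cox_fit(data, keep)
    p <- fit$table$p_value
    if (all(p < alpha) || length(keep) == 1 && p[1] < alpha) break
    worst <- which.max(p)  # which.max takes the first on ties
    if (p[worst] < alpha) break
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
    if (length(keep) == 0) return(list(univariate = uni, final = NULL,
                                       removed = removed))
  }
  list(univariate = uni, final = fit, removed = removed)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator with tie correction (ties count one half),
#' equal to the trapezoidal area under the empirical ROC curve. Higher
#' scores are taken to indicate higher risk.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes (1/TRUE = event).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as one half
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong comparison of two paired AUCs
#'
#' Nonparametric comparison of two correlated AUCs measured on the same
#' subjects, using DeLong structural components for the variance and
#' covariance and a two-sided z-test on the AUC difference.
#'
#' @param scores_1,scores_2 Paired risk scores on the same subjects.
#' @param outcomes Binary outcomes.
#' @return List with `auc_1`, `auc_2`, `cov_matrix` (2x2), `z`, `p_value`.
#' @export
delong_test <- function(scores_1, scores_2, outcomes) {
  y <- as.logical(outcomes)
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  r1 <- pROC::roc(y, scores_1, direction = "<", quiet = TRUE)
  r2 <- pROC::roc(y, scores_2, direction = "<", quiet = TRUE)
  v1 <- pROC::var(r1, method = "delong")
  v2 <- pROC::var(r2, method = "delong")
  cv <- pROC::cov(r1, r2, method = "delong")
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  var_diff <- v1 + v2 - 2 * cv
  if (var_diff < 1e-12) {
    if (abs(a1 - a2) < 1e-12)
      return(list(auc_1 = a1, auc_2 = a2,
                  cov_matrix = matrix(c(v1, cv, cv, v2), 2), z = 0,
                  p_value = 1))
    stop("degenerate variance: DeLong test undefined")
  }
  z <- (a1 - a2) / sqrt(var_diff)
  list(auc_1 = a1, auc_2 = a2,
       cov_matrix = matrix(c(v1, cv, cv, v2), 2), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' DeLong confidence interval for a single AUC
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(scores, outcomes, level = 0.95) {
  y <- as.logical(outcomes)
  r <- pROC::roc(y, scores, direction = "<", quiet = TRUE)
  v <- pROC::var(r, method = "delong")
  a <- as.numeric(pROC::auc(r))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = a, variance = v,
       ci_low = max(0, a - zq * sqrt(v)), ci_high = min(1, a + zq * sqrt(v)))
}

#' Youden-optimal cutoff
#'
#' Scans every observed score as a threshold (classification rule:
#' score >= cutoff predicts the event) and returns the cutoff that
#' maximizes Youden's J = sensitivity + specificity - 1. Among tied
#' cutoffs the smallest is chosen, favoring sensitivity.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @return List with `cutoff`, `youden_index`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  cand <- sort(unique(scores))
  best <- list(j = -Inf)
  for (ct in cand) {
    sens <- mean(scores[y] >= ct)
    spec <- mean(scores[!y] < ct)
    j <- sens + spec - 1
    if (j > best$j)
      best <- list(j = j, cutoff = ct, sens = sens, spec = spec)
  }
  list(cutoff = best$cutoff, youden_index = best$j,
       sensitivity = best$sens, specificity = best$spec)
}

#' Confusion-matrix metrics at a cutoff
#'
#' Sensitivity, specificity, PPV and NPV of the score >= cutoff rule.
#' An empty predicted-positive or predicted-negative margin yields `NaN`
#' for the affected predictive value rather than a silent zero.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @param cutoff Classification threshold.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` and the
#'   2x2 counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, outcomes, cutoff) {
  y <- as.logical(outcomes)
  pred <- scores >= cutoff
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp == 0) NaN else tp / (tp + fp),
       npv = if (tn + fn == 0) NaN else tn / (tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Logistic recalibration of a score to event probabilities
#'
#' Fits a univariable logistic regression of the outcome on the score by
#' maximum likelihood and returns the fitted event probabilities. Raw
#' prognostic scores are not probabilities; this is the standard mapping
#' before calibration and overall-performance statistics. Under complete
#' separation the probabilities are clamped away from 0/1 and the result
#' is flagged.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @return List with `probabilities` (monotone in the score),
#'   `model` (the `glm` fit), `separation` (logical flag).
#' @export
score_to_risk <- function(scores, outcomes) {
  y <- as.integer(as.logical(outcomes))
  if (!any(y == 1) || !any(y == 0)) stop("both outcome classes required")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p <- pmin(pmax(stats::fitted(fit), 1e-10), 1 - 1e-10)
  list(probabilities = unname(p), model = fit, separation = sep)
}

# equal-count risk bins; ties broken by original order (stable sort)
risk_bins <- function(probabilities, groups) {
  ord <- order(probabilities)
  split(ord, cut(seq_along(ord), groups, labels = FALSE))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into equal-count bins by predicted risk (default
#' deciles; ties broken by input order) and compares observed with
#' expected events via the chi-square statistic
#' sum (O - E)^2 / (E (1 - E/n)) on `groups - 2` degrees of freedom.
#' Bins whose expected count is zero are merged into their neighbor,
#' with a warning.
#'
#' @param probabilities Predicted event probabilities.
#' @param outcomes Binary outcomes.
#' @param groups Number of risk bins (default 10).
#' @return List with `statistic`, `df`, `p_value`, `groups_used`.
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 10) {
  y <- as.integer(as.logical(outcomes))
  stopifnot(groups >= 2, length(y) >= groups)
  bins <- risk_bins(probabilities, groups)
  obs <- vapply(bins, function(i) sum(y[i]), numeric(1))
  expd <- vapply(bins, function(i) sum(probabilities[i]), numeric(1))
  nn <- vapply(bins, length, numeric(1))
  empty <- expd == 0 | expd == nn
  if (any(empty)) {
    warning("merging risk bins with degenerate expected counts")
    keep <- !empty
    merge_to <- max(which(keep))
    obs[merge_to] <- obs[merge_to] + sum(obs[empty])
    expd[merge_to] <- expd[merge_to] + sum(expd[empty])
    nn[merge_to] <- nn[merge_to] + sum(nn[empty])
    obs <- obs[keep]; expd <- expd[keep]; nn <- nn[keep]
  }
  stat <- sum((obs - expd)^2 / (expd * (1 - expd / nn)))
  df <- max(length(obs) - 2, 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups_used = length(obs))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better.
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param outcomes Binary outcomes.
#' @return Brier score in [0, 1].
#' @export
brier <- function(probabilities, outcomes) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  mean((probabilities - as.numeric(as.logical(outcomes)))^2)
}

#' Nagelkerke pseudo-R-squared of a logistic recalibration
#'
#' (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n)) from the null and fitted
#' likelihoods of the [score_to_risk()] model; in [0, 1], approaching 1
#' in the separation limit.
#'
#' @param model A fitted binomial `glm` (e.g. from [score_to_risk()]).
#' @return Nagelkerke pseudo-R-squared.
#' @export
nagelkerke_r2 <- function(model) {
  n <- length(model$y)
  ll1 <- as.numeric(stats::logLik(model))
  ll0 <- as.numeric(stats::logLik(stats::update(model, . ~ 1)))
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  cs / (1 - exp(2 * ll0 / n))
}

#' Calibration curve
#'
#' Equal-count bins of predicted risk, each summarized by its mean
#' predicted probability and observed event rate. The count-weighted
#' mean of the observed rates equals the overall event rate.
#'
#' @param probabilities Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param bins Number of bins (default 10).
#' @return Data frame with `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_curve <- function(probabilities, outcomes, bins = 10) {
  stopifnot(bins >= 2)
  y <- as.numeric(as.logical(outcomes))
  bb <- risk_bins(probabilities, bins)
  data.frame(
    bin = seq_along(bb),
    n = vapply(bb, length, numeric(1)),
    mean_predicted = vapply(bb, function(i) mean(probabilities[i]), numeric(1)),
    observed_rate = vapply(bb, function(i) mean(y[i]), numeric(1)),
    row.names = NULL)
}

#' Full performance panel for one prognostic score
#'
#' Discrimination (AUC with DeLong 95% CI, Youden cutoff, sensitivity,
#' specificity, PPV, NPV), calibration (Hosmer-Lemeshow, calibration
#' bins) and overall performance (Brier, Nagelkerke R-squared) of a
#' score against a binary outcome, with calibration statistics computed
#' on logistic-recalibrated probabilities.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @param hl_groups Hosmer-Lemeshow bins (default 10).
#' @return A list of class `score_performance` with `summary` (one-row
#'   data frame: auc, auc_ci_low, auc_ci_high, youden_index, cutoff,
#'   sensitivity, specificity, ppv, npv, brier, r_squared, hl_statistic,
#'   hl_p) and `calibration_bins`.
#' @export
score_performance <- function(scores, outcomes, hl_groups = 10) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  outcomes <- as.logical(outcomes)[ok]
  ci <- auc_ci(scores, outcomes)
  yc <- youden_cutoff(scores, outcomes)
  cm <- confusion_metrics(scores, outcomes, yc$cutoff)
  sr <- score_to_risk(scores, outcomes)
  hl <- hosmer_lemeshow(sr$probabilities, outcomes, hl_groups)
  structure(list(
    summary = data.frame(
      auc = ci$auc, auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
      youden_index = yc$youden_index, cutoff = yc$cutoff,
      sensitivity = yc$sensitivity, specificity = yc$specificity,
      ppv = cm$ppv, npv = cm$npv,
      brier = brier(sr$probabilities, outcomes),
      r_squared = nagelkerke_r2(sr$model),
      hl_statistic = hl$statistic, hl_p = hl$p_value),
    calibration_bins = calibration_curve(sr$probabilities, outcomes)),
    class = "score_performance")
}
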