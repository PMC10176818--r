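test_that("group comparisons route by distribution and handle categories", {
  set.seed(50)
  # identical numeric groups: no evidence of a difference
  x <- rlnorm(60, 1, 0.8)
  same <- group_compare(x, x)
  expect_gt(same$p_value, 0.99)
  # heavily skewed data routes to Mann-Whitney
  a <- rlnorm(80, 0, 1.2); b <- rlnorm(80, 0.8, 1.2)
  expect_equal(group_compare(a, b)$test, "mann-whitney")
  # normal data routes to the t-test
  a <- rnorm(80, 10, 1); b <- rnorm(80, 10.5, 1)
  expect_equal(group_compare(a, b)$test, "t-test")
  # balanced contingency table: chi-square statistic 0, p = 1
  flat <- group_compare(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # the published mortality contrast (deaths/survivors, ACLF vs AD)
  mort <- group_compare(rbind(c(79, 102), c(13, 141)))
  expect_equal(mort$test, "chi-square")
  expect_lt(mort$p_value, 0.001)
  expect_error(group_compare(numeric(0), 1:5), ">= 2 observations")
})

test_that("Kaplan-Meier estimate matches the product-limit by hand", {
  # no censoring before t: S(t) = 1 - d/n
  expect_equal(km_estimate(c(rep(10, 79), rep(42, 102)),
                           c(rep(1, 79), rep(0, 102)), 42),
               102 / 181)
  # no events at all
  expect_equal(km_estimate(rep(42, 20), rep(0, 20), 42), 1)
  # hand product-limit with intermediate censoring: (2/3) * (0/1)
  expect_equal(km_estimate(c(1, 2, 3), c(1, 0, 1), 3), 0)
  expect_error(km_estimate(numeric(0), numeric(0), 42), "empty")
})

test_that("log-rank test agrees with the hand-tabulated statistic", {
  # identical groups split at random: statistic near 0 is not guaranteed,
  # but two copies of the same group give exactly 0
  tm <- c(1, 3, 5, 7, 9); ev <- c(1, 1, 0, 1, 0)
  lr <- log_rank(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)
  # fully separated event times vs the observed-minus-expected oracle
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  group <- rep(c("a", "b"), each = 3)
  lr <- log_rank(time, event, group)
  expect_equal(lr$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # k-group version uses k - 1 degrees of freedom
  lr4 <- log_rank(rexp(40) + 0.1, rep(1, 40), rep(1:4, each = 10))
  expect_equal(lr4$df, 3)
  expect_error(log_rank(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("Cox fit maximizes the partial likelihood", {
  expect_error(cox_fit(data.frame(time = 1:4, event = c(1, 1, 0, 1),
                                  x = rep(1, 4)), "x"), "constant")
  # 6-subject hand dataset, untied times: compare against direct
  # maximization of the hand-written partial likelihood
  d <- data.frame(time = c(1.1, 2.3, 3.7, 4.2, 5.9, 6.4),
                  event = c(1, 1, 0, 1, 1, 0),
                  x = c(1, 0, 1, 0, 1, 0))
  fit <- cox_fit(d, "x")
  beta_hat <- stats::optimize(function(b)
    -oracle_cox_loglik(b, d$time, d$event, d$x), c(-5, 5))$minimum
  expect_equal(fit$table$coef, beta_hat, tolerance = 1e-5)
  expect_equal(fit$loglik,
               oracle_cox_loglik(fit$table$coef, d$time, d$event, d$x),
               tolerance = 1e-8)
  expect_equal(fit$table$hazard_ratio, exp(fit$table$coef))
  expect_true(fit$table$ci_low <= fit$table$hazard_ratio &
                fit$table$hazard_ratio <= fit$table$ci_high)
})

test_that("Cox fit recovers a known log-hazard on exponential data", {
  set.seed(52)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  beta <- log(2.12)
  t0 <- rexp(n, 0.002 * exp(beta * x))
  d <- data.frame(time = pmin(t0, 42), event = as.integer(t0 < 42), x = x)
  fit <- cox_fit(d, "x")
  se <- sqrt(diag(fit$model$var))[1]
  expect_lt(abs(fit$table$coef - beta), 3 * se)
})

test_that("perfect separation in Cox is flagged, not silent", {
  d <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                  event = c(1, 1, 1, 1, 1, 1),
                  x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- cox_fit(d, "x"), "monotone")
  expect_true(any(fit$table$flagged))
})

test_that("backward stepwise keeps the signal and drops the noise", {
  set.seed(53)
  n <- 800
  strong <- rbinom(n, 1, 0.5)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  t0 <- rexp(n, 0.01 * exp(1.2 * strong))
  d <- data.frame(time = pmin(t0, 42), event = as.integer(t0 < 42),
                  strong = strong, noise1 = noise1, noise2 = noise2)
  res <- backward_stepwise(d, c("noise1", "strong", "noise2"))
  expect_true("strong" %in% res$final$covariates)
  expect_true(all(res$final$table$p_value < 0.05))
  # all-noise candidates: empty model, not an error
  d2 <- d; d2$event <- rbinom(n, 1, 0.3)
  res2 <- backward_stepwise(d2, c("noise1", "noise2"))
  if (is.null(res2$final)) {
    expect_equal(nrow(res2$univariate), 2)
  } else {
    expect_true(all(res2$final$table$p_value < 0.05))
  }
})

test_that("stepwise removal order matches the all-candidates Wald ranking", {
  set.seed(54)
  n <- 600
  x1 <- rbinom(n, 1, 0.5)
  x2 <- x1 + rnorm(n, 0, 0.6)   # correlated shadow of x1
  x3 <- rnorm(n)
  t0 <- rexp(n, 0.01 * exp(1.0 * x1 + 0.25 * x3))
  d <- data.frame(time = pmin(t0, 42), event = as.integer(t0 < 42),
                  x1 = x1, x2 = x2, x3 = x3)
  res <- backward_stepwise(d, c("x1", "x2", "x3"))
  # replay the elimination by brute force from the screened set
  keep <- res$univariate$term[res$univariate$p_value < 0.05]
  removed <- character()
  while (length(keep) > 0) {
    tab <- cox_fit(d, keep)$table
    if (all(tab$p_value < 0.05)) break
    worst <- keep[which.max(tab$p_value)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  expect_equal(res$removed, removed)
  expect_setequal(res$final$covariates, keep)
})

test_that("AUC equals the pair-enumeration oracle and its invariances", {
  expect_error(roc_auc(c(3, 5), c(1, 1)), "both outcome classes")
  expect_equal(roc_auc(c(1, 4, 3, 5), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(55)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE)  # force ties
    outcomes <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- roc_auc(scores, outcomes)
    expect_equal(a, oracle_auc(scores, outcomes))
    # invariance under strictly monotone transform; complement rule
    expect_equal(roc_auc(exp(scores / 3), outcomes), a)
    expect_equal(roc_auc(-scores, outcomes), 1 - a)
  }
})

test_that("DeLong comparison is exact under self- and rank-equivalence", {
  set.seed(56)
  y <- rbinom(120, 1, 0.4)
  s <- rnorm(120) + y
  self <- delong_test(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  mono <- delong_test(s, exp(s), y)
  expect_equal(mono$auc_1, mono$auc_2)
  expect_equal(mono$p_value, 1)
  expect_equal(self$auc_1, roc_auc(s, y))
  two <- delong_test(s, s + rnorm(120, 0, 2), y)
  expect_true(two$p_value >= 0 && two$p_value <= 1)
  expect_equal(dim(two$cov_matrix), c(2L, 2L))
})

test_that("DeLong variance of a single AUC agrees with the bootstrap", {
  set.seed(57)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  s <- rnorm(n) + 1.1 * y
  v_delong <- auc_ci(s, y)$variance
  B <- 2000
  boot <- replicate(B, {
    i <- sample.int(n, n, replace = TRUE)
    if (sum(y[i]) == 0 || sum(y[i]) == n) NA_real_ else roc_auc(s[i], y[i])
  })
  v_boot <- stats::var(boot, na.rm = TRUE)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.10)
  ci <- auc_ci(s, y)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
})

test_that("Youden scan matches exhaustive threshold enumeration", {
  # perfectly separating scores
  yc <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(yc$youden_index, 1.0)
  set.seed(58)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    scores <- sample(1:6, n, replace = TRUE)
    outcomes <- c(0, 1, rbinom(n - 2, 1, 0.5))
    yc <- youden_cutoff(scores, outcomes)
    # brute force over every candidate threshold
    cands <- sort(unique(scores))
    js <- vapply(cands, function(ct) {
      mean(scores[outcomes == 1] >= ct) + mean(scores[outcomes == 0] < ct) - 1
    }, numeric(1))
    expect_equal(yc$youden_index, max(js))
    expect_equal(yc$cutoff, cands[which.max(js)])  # smallest among ties
    expect_equal(yc$youden_index, yc$sensitivity + yc$specificity - 1)
  }
})

test_that("confusion metrics reproduce hand-computed 2x2 ratios", {
  # perfect classifier
  cm <- confusion_metrics(c(1, 1, 9, 9), c(0, 0, 1, 1), 5)
  expect_equal(unlist(cm[1:4]), c(sensitivity = 1, specificity = 1,
                                  ppv = 1, npv = 1))
  # cutoff below every score
  cm <- confusion_metrics(c(2, 3, 4), c(0, 1, 1), 1)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  expect_true(is.nan(cm$npv))  # empty predicted-negative margin flagged
  # TP 55, FN 24, TN 72, FP 30
  scores <- c(rep(10, 55), rep(1, 24), rep(1, 72), rep(10, 30))
  outcomes <- c(rep(1, 79), rep(0, 102))
  cm <- confusion_metrics(scores, outcomes, 10)
  expect_equal(cm$sensitivity, 55 / 79)
  expect_equal(cm$specificity, 72 / 102)
  expect_equal(cm$ppv, 55 / 85)
  expect_equal(cm$npv, 72 / 96)
})

test_that("logistic recalibration is monotone and mean-calibrated", {
  set.seed(59)
  n <- 400
  s <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-0.5 + 1.3 * s))
  sr <- score_to_risk(s, y)
  expect_equal(mean(sr$probabilities), mean(y), tolerance = 1e-8)
  expect_true(all(diff(sr$probabilities[order(s)]) >= 0))
  # matches an independent IRLS fit to high precision
  irls <- function(x, y, iters = 50) {
    b <- c(0, 0); X <- cbind(1, x)
    for (i in seq_len(iters)) {
      p <- stats::plogis(X %*% b)
      W <- as.vector(p * (1 - p))
      b <- b + solve(t(X) %*% (W * X), t(X) %*% (y - p))
    }
    as.vector(b)
  }
  expect_equal(unname(stats::coef(sr$model)), irls(s, y), tolerance = 1e-6)
  # outcome independent of score: probabilities collapse to prevalence
  y0 <- rbinom(n, 1, 0.3)
  sr0 <- score_to_risk(rnorm(n), y0)
  expect_lt(diff(range(sr0$probabilities)), 0.2)
})

test_that("Hosmer-Lemeshow statistic is zero under exact calibration", {
  # two bins, observed equal to expected in each
  p <- c(rep(0.2, 10), rep(0.8, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(hl$statistic, 0)
  # seeded miscalibrated set vs independent hand tabulation
  set.seed(60)
  n <- 500
  pr <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, stats::plogis(stats::qlogis(pr) + 0.8))
  hl <- hosmer_lemeshow(pr, y, groups = 10)
  ord <- order(pr)
  bins <- split(ord, cut(seq_along(ord), 10, labels = FALSE))
  stat <- sum(vapply(bins, function(i) {
    O <- sum(y[i]); E <- sum(pr[i]); nn <- length(i)
    (O - E)^2 / (E * (1 - E / nn))
  }, numeric(1)))
  expect_equal(hl$statistic, stat)
  expect_equal(hl$df, 8)
})

test_that("Brier score equals the mean squared probability error", {
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0)
  expect_equal(brier(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_error(brier(c(1.2, 0.5), c(1, 0)), "probabilities")
})

test_that("Nagelkerke R2 matches the likelihood formula and its limits", {
  set.seed(61)
  n <- 300
  s <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(1.5 * s))
  sr <- score_to_risk(s, y)
  r2 <- nagelkerke_r2(sr$model)
  ll1 <- as.numeric(stats::logLik(sr$model))
  ll0 <- sum(stats::dbinom(y, 1, mean(y), log = TRUE))
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  expect_equal(r2, cs / (1 - exp(2 * ll0 / n)), tolerance = 1e-10)
  expect_true(r2 > 0 && r2 < 1)
  # independent outcome: near zero
  y0 <- rbinom(n, 1, 0.4)
  r2_null <- nagelkerke_r2(score_to_risk(rnorm(n), y0)$model)
  expect_lt(r2_null, 0.05)
})

test_that("calibration bins conserve the overall event rate", {
  set.seed(62)
  n <- 500
  pr <- runif(n)
  y <- rbinom(n, 1, pr)
  cc <- calibration_curve(pr, y, bins = 10)
  expect_equal(sum(cc$n), n)
  expect_equal(sum(cc$observed_rate * cc$n) / n, mean(y))
  # bin contents match an independent sort-and-split
  ord <- order(pr)
  first_bin <- ord[1:cc$n[1]]
  expect_equal(cc$mean_predicted[1], mean(pr[first_bin]))
  expect_true(all(diff(cc$mean_predicted) > 0))
})

test_that("the performance panel assembles consistent metrics", {
  set.seed(63)
  n <- 300
  y <- rbinom(n, 1, 0.35)
  s <- rnorm(n) + 0.9 * y
  sp <- score_performance(s, y)
  sm <- sp$summary
  expect_true(sm$auc > 0.5 && sm$auc <= 1)
  expect_equal(sm$youden_index, sm$sensitivity + sm$specificity - 1)
  expect_true(sm$auc_ci_low <= sm$auc && sm$auc <= sm$auc_ci_high)
  expect_true(sm$brier >= 0 && sm$brier <= 0.25)
  expect_equal(sum(sp$calibration_bins$n), n)
})
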