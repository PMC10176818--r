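# Independent brute-force oracles, coded directly from the clinical
# definitions and kept free of the package's implementation paths.

# ACLF grade from a failure vector (named logical over the six organs),
# a creatinine stratum and an HE stratum -- a literal transcription of
# the diagnostic rules.
oracle_grade <- function(fails, creatinine, he_grade) {
  k <- sum(fails)
  if (k >= 3) return(3L)
  if (k == 2) return(2L)
  if (k == 0) return(0L)
  cr_band <- creatinine >= 1.5 & creatinine < 2.0
  he_mild <- he_grade >= 1 && he_grade <= 2
  if (fails["kidney"]) return(1L)
  if (fails["brain"]) return(if (cr_band) 1L else 0L)
  # single failure of liver, coagulation, circulation or respiration
  if (cr_band || he_mild) return(1L) else return(0L)
}

# AUC by exhaustive enumeration of case-control pairs (ties count 1/2)
oracle_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  cases <- scores[y]; controls <- scores[!y]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Cox partial log-likelihood for a single covariate with untied times
# (Breslow form; equals Efron when no ties)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-group log-rank statistic by hand tabulation over event times
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small hand-written cohort whose scores/grades are verifiable by hand
hand_cohort <- function() {
  data.frame(
    patient_id = sprintf("H%02d", 1:6),
    age = c(55, 60, 45, 70, 50, 65),
    sex = c("male", "female", "male", "male", "female", "male"),
    bilirubin = c(1.0, 2.5, 13.0, 5.0, 1.5, 12.5),
    albumin = c(4.0, 2.9, 2.0, 3.0, 3.6, 2.5),
    inr = c(1.0, 1.8, 2.6, 2.0, 1.2, 3.0),
    creatinine = c(0.8, 1.0, 1.6, 2.8, 0.9, 3.6),
    sodium = c(140, 130, 128, 136, 138, 125),
    potassium = c(4.2, 4.5, 5.0, 4.8, 4.0, 5.5),
    wbc = c(7.7, 9.0, 13.9, 15.0, 6.0, 20.0),
    hemoglobin = c(9.5, 8.1, 7.5, 8.0, 10.0, 7.0),
    mean_arterial_pressure = c(80, 75, 72, 68, 85, 60),
    pao2_fio2 = NA_real_,
    spo2_fio2 = c(460, 300, 246, 210, 440, 150),
    he_grade = c(0L, 1L, 2L, 0L, 0L, 4L),
    ascites_grade = c(0L, 1L, 2L, 1L, 0L, 2L),
    on_vasopressors = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    on_mechanical_ventilation = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    mv_airway_protection_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    on_rrt = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    time = c(42, 42, 10.5, 20.2, 42, 3.1),
    event = c(0L, 0L, 1L, 1L, 0L, 1L)
  )
}
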