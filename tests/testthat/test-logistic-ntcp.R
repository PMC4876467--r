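test_that("the adequate-follow-up rule keeps and drops the right lobes", {
  co <- make_eligibility_cohort(n_patients = 132, n_censored_early = 21,
                                n_injured_lobes = 21)
  el <- eligibility_filter(co, window = 50)
  expect_equal(attr(el, "counts")$n_kept, 222)
  expect_equal(attr(el, "counts")$n_dropped, 42)
  expect_equal(sum(el$event), 21)

  expect_equal(nrow(eligibility_filter(co, window = 0)), nrow(co))

  # an injury observed before the patient's later censoring is retained...
  lb <- make_lobes(c("A", "A"), time_months = c(19, 30), event = c(1, 0),
                   censor_reason = c(NA, "death"))
  expect_equal(sum(eligibility_filter(lb, 50)$event), 1)
  # ...unless the strict-exclusion toggle is on
  expect_equal(nrow(eligibility_filter(lb, 50, strict = TRUE)), 0)
})

test_that("logistic fitting flags complete separation", {
  lb <- make_lobes(sprintf("P%d", 1:8), time_months = rep(60, 8),
                   event = c(0, 0, 0, 0, 1, 1, 1, 1),
                   censor_reason = c(rep("end_of_followup", 4), rep(NA, 4)),
                   d_max = 1:8 + 60)
  expect_warning(f <- fit_logistic(lb, "d_max"), "separation")
  expect_true(f$separation)
  lb1 <- lb; lb1$event <- 0L; lb1$censor_reason <- "end_of_followup"
  expect_error(fit_logistic(lb1, "d_max"), "both outcome classes")
})

test_that("permuted doses give a null slope at the expected rate", {
  set.seed(202)
  calm <- 0; nrep <- 30
  for (i in seq_len(nrep)) {
    n <- 400
    dose <- rnorm(n, 68, 5)
    y <- rbinom(n, 1, 0.12)                    # independent of dose
    lb <- make_lobes(sprintf("P%04d", 1:n), time_months = rep(60, n),
                     event = y,
                     censor_reason = ifelse(y == 1, NA, "end_of_followup"),
                     d_max = dose)
    f <- fit_logistic(lb, "d_max")
    if (abs(f$z[2]) < 2) calm <- calm + 1
  }
  expect_gte(calm / nrep, 0.9)
})

test_that("logistic parameters are recovered from their own model", {
  set.seed(99)
  b1 <- (qlogis(0.5) - qlogis(0.1)) / (80.9 - 67.4)
  b0 <- -80.9 * b1
  n <- 5000
  dose <- rnorm(n, 72, 7)
  y <- rbinom(n, 1, plogis(b0 + b1 * dose))
  lb <- make_lobes(sprintf("P%05d", 1:n), time_months = rep(60, n),
                   event = y,
                   censor_reason = ifelse(y == 1, NA, "end_of_followup"),
                   d_max = dose)
  f <- fit_logistic(lb, "d_max")
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$b0 - b0), 3 * se[1])
  expect_lt(abs(f$b1 - b1), 3 * se[2])
})

test_that("anchor calibration reproduces the published tolerance table", {
  f <- logistic_from_anchors(80.9, 0.5, 67.4, 0.1, dose_variable = "d_1cc")
  td <- tolerance_dose(f, c(0.01, 0.05, 0.20, 0.30))
  expect_equal(round(td$td, 1), c(52.7, 62.8, 72.4, 75.7))
  fm <- logistic_from_anchors(82.1, 0.5, 72.4, 0.1, dose_variable = "d_max")
  tdm <- tolerance_dose(fm, c(0.20, 0.30))
  expect_equal(round(tdm$td, 1), c(76.0, 78.4))
})

test_that("tolerance-dose inversion satisfies its exact identities", {
  f <- logistic_from_anchors(80.9, 0.5, 67.4, 0.1)
  ps <- seq(0.02, 0.98, by = 0.08)
  td <- tolerance_dose(f, ps)$td
  expect_true(all(diff(td) > 0))
  expect_true(all(abs(logistic_response(f, td) - ps) < 1e-9))
  # symmetry point: b0 = 0 puts TD50 at zero dose for any slope
  f0 <- f; f0$b0 <- 0
  expect_equal(tolerance_dose(f0, 0.5)$td, 0)
  expect_error(tolerance_dose(f, 1.2), "between 0 and 1")
})

test_that("dose shifts translate tolerance doses without touching SEs", {
  set.seed(17)
  n <- 600
  dose <- rnorm(n, 70, 6)
  y <- rbinom(n, 1, plogis(-13 + 0.18 * dose))
  mk <- function(d) make_lobes(sprintf("P%04d", 1:n),
                               time_months = rep(60, n), event = y,
                               censor_reason = ifelse(y == 1, NA,
                                                      "end_of_followup"),
                               d_max = d)
  f1 <- fit_logistic(mk(dose), "d_max")
  f2 <- fit_logistic(mk(dose + 7), "d_max")
  t1 <- tolerance_dose(f1, c(0.1, 0.5))
  t2 <- tolerance_dose(f2, c(0.1, 0.5))
  expect_equal(t2$td, t1$td + 7, tolerance = 1e-6)
  expect_equal(t2$se, t1$se, tolerance = 1e-6)
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  set.seed(23)
  n <- 1200
  dose <- rnorm(n, 70, 6)
  y <- rbinom(n, 1, plogis(-13 + 0.18 * dose))
  lb <- make_lobes(sprintf("P%04d", 1:n), time_months = rep(60, n),
                   event = y,
                   censor_reason = ifelse(y == 1, NA, "end_of_followup"),
                   d_max = dose)
  f <- fit_logistic(lb, "d_max")
  td <- tolerance_dose(f, c(0.2, 0.5))
  ch <- chol(f$vcov)
  draws <- matrix(rnorm(2 * 2000), 2000, 2) %*% ch
  for (i in 1:2) {
    b0s <- f$b0 + draws[, 1]; b1s <- f$b1 + draws[, 2]
    boot_sd <- sd((qlogis(td$p[i]) - b0s) / b1s)
    expect_lt(abs(td$se[i] - boot_sd) / boot_sd, 0.1)
  }
})

test_that("error bounds widen toward extreme response probabilities", {
  set.seed(41)
  n <- 800
  dose <- rnorm(n, 70, 6)
  y <- rbinom(n, 1, plogis(-13 + 0.18 * dose))
  lb <- make_lobes(sprintf("P%04d", 1:n), time_months = rep(60, n),
                   event = y,
                   censor_reason = ifelse(y == 1, NA, "end_of_followup"),
                   d_max = dose)
  f <- fit_logistic(lb, "d_max")
  td <- tolerance_dose(f, c(0.01, 0.30))
  expect_gt(td$se[1], td$se[2])
  crv <- dose_response_curve(f)
  expect_equal(nrow(crv), 99)
  expect_true(all(diff(crv$td) > 0))
  expect_true(all(crv$td_lower < crv$td & crv$td < crv$td_upper))
  vert <- dose_response_curve(f, orientation = "vertical")
  expect_true(all(vert$p_lower >= 0 & vert$p_upper <= 1))
  expect_equal(logistic_response(f, tolerance_dose(f, 0.5)$td), 0.5)
})

test_that("dose binning uses half-open intervals anchored at zero", {
  lb <- make_lobes(sprintf("P%d", 1:3), time_months = rep(60, 3),
                   event = c(0, 1, 0),
                   censor_reason = c("end_of_followup", NA,
                                     "end_of_followup"),
                   d_max = c(69.0, 70.0, 71.0))
  b <- binned_incidence(lb, "d_max", width = 2.5)
  expect_equal(nrow(b), 2)
  expect_equal(b$lower, c(67.5, 70.0))
  expect_equal(b$n, c(1, 2))
  expect_equal(b$events, c(0, 1))
  one <- binned_incidence(lb, "d_max", width = 50)
  expect_equal(nrow(one), 1)
  expect_equal(one$rate, 1 / 3)
  expect_error(binned_incidence(lb, "d_max", width = 0), "positive")
})

test_that("binned crude rates bracket the fitted sigmoid", {
  lb <- generate_cohort(quick_cfg(n_patients = 400, seed = 61))$lobes
  el <- eligibility_filter(lb)
  f <- fit_logistic(el, "d_1cc")
  b <- binned_incidence(el, "d_1cc", width = 2.5)
  b <- b[b$n >= 5, ]
  phat <- logistic_response(f, b$midpoint)
  within <- abs(b$rate - phat) <= 2 * sqrt(phat * (1 - phat) / b$n) + 1e-9
  expect_gt(mean(within), 0.5)
})
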