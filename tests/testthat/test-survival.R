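# Kaplan-Meier, log-rank, Cox.  The survival package serves as an
# independent oracle wherever it implements the same estimator.

test_that("Kaplan-Meier handles censoring, ties and degenerate input", {
  expect_error(km_estimate(c(1, -2), c(1, 1)), "positive")
  # all censored: S identically 1
  km <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_identical(nrow(km$curve), 0L)
  expect_identical(km_survival_at(km, c(0, 4, 100)), c(1, 1, 1))
  # n = 4, one death at t = 10: S drops to 0.75
  km2 <- km_estimate(c(10, 12, 15, 20), c(1, 0, 0, 0))
  expect_identical(km_survival_at(km2, c(9.9, 10, 50)), c(1, 0.75, 0.75))
  # ties decrement simultaneously
  km3 <- km_estimate(c(5, 5, 5, 8), c(1, 1, 0, 0))
  expect_identical(km_survival_at(km3, 5), 0.5)
  # horizon truncation censors later records
  km4 <- km_estimate(c(5, 30), c(1, 1), horizon = 24)
  expect_identical(km4$curve$time, 5)
})

test_that("without censoring the KM estimate is the empirical survival", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    time <- round(rexp(n, 0.2), 2) + 0.01
    km <- km_estimate(time, rep(1, n))
    at <- sort(unique(time))
    expect_equal(km_survival_at(km, at),
                 vapply(at, function(t) mean(time > t), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("KM is invariant to record order and matches survfit", {
  set.seed(3)
  time <- round(rexp(60, 0.1), 1) + 0.1
  event <- rbinom(60, 1, 0.6)
  km <- km_estimate(time, event)
  perm <- sample(60)
  expect_identical(km_estimate(time[perm], event[perm]), km)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  ref <- summary(sf, times = km$curve$time)
  expect_equal(km$curve$surv, ref$surv, tolerance = 1e-12)
})

test_that("median survival follows the <= 0.5 convention", {
  km_high <- km_estimate(c(2, 4, 6, 8, 10), c(1, 0, 0, 0, 0))  # S stays 0.8
  expect_identical(median_survival(km_high), Inf)
  # S drops exactly to 0.5 at t = 12
  km_half <- km_estimate(c(12, 12, 20, 20), c(1, 1, 0, 0))
  expect_identical(median_survival(km_half), 12)
  # exponential cohort: median ~ ln 2 / lambda
  set.seed(5)
  lam <- 0.05
  km_exp <- km_estimate(rexp(4000, lam), rep(1, 4000))
  expect_lt(abs(median_survival(km_exp) - log(2) / lam) / (log(2) / lam), 0.1)
})

test_that("log-rank statistic matches a hand tabulation and survdiff", {
  # 6-patient worked example: deaths at 1,2,3 in A and 4,5,6 in B
  tA <- c(1, 2, 3); tB <- c(4, 5, 6)
  lr <- logrank_test(tA, c(1, 1, 1), tB, c(1, 1, 1))
  # hand tabulation of O-E and V over the six risk sets
  o1 <- e1 <- v <- 0
  time <- c(tA, tB); grp <- rep(1:2, each = 3)
  for (t in 1:6) {
    at <- time >= t; n <- sum(at); n1 <- sum(at & grp == 1)
    d1 <- as.integer(t <= 3)
    o1 <- o1 + d1; e1 <- e1 + n1 / n
    if (n > 1) v <- v + (n1 / n) * (1 - n1 / n)
  }
  expect_lt(abs(lr$statistic - (o1 - e1)^2 / v), 1e-10)
  sd <- survival::survdiff(survival::Surv(c(tA, tB), rep(1, 6)) ~ grp)
  expect_lt(abs(lr$statistic - sd$chisq), 1e-10)

  # exchangeable null: identical groups give statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_identical(lr0$statistic, 0)
  expect_identical(lr0$p_value, 1)
  # group swap leaves the statistic unchanged
  set.seed(10)
  t1 <- rexp(30, 0.1); e1s <- rbinom(30, 1, 0.7)
  t2 <- rexp(25, 0.2); e2s <- rbinom(25, 1, 0.7)
  expect_equal(logrank_test(t1, e1s, t2, e2s)$statistic,
               logrank_test(t2, e2s, t1, e1s)$statistic, tolerance = 1e-12)
  expect_warning(z <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
  expect_identical(z$p_value, 1)
})

test_that("Cox fit matches coxph for both tie conventions", {
  set.seed(70)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    time <- round(rexp(n, 0.1), 1) + 0.5   # rounding forces ties
    event <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (sum(event[grp == 1]) == 0 || sum(event[grp == 0]) == 0) next
    for (ties in c("breslow", "efron")) {
      f <- cox_fit(time, event, grp, ties = ties)
      ref <- survival::coxph(survival::Surv(time, event) ~ grp, ties = ties)
      expect_lt(abs(f$beta - unname(coef(ref))), 1e-6)
      expect_lt(abs(f$se - sqrt(unname(ref$var[1, 1]))), 1e-6)
      # first-order optimality
      expect_lt(abs(f$score_at_solution), 1e-6)
      # CI brackets the HR
      expect_true(f$ci[1] <= f$hr && f$hr <= f$ci[2])
    }
  }
})

test_that("Cox fit is antisymmetric under group relabelling", {
  set.seed(71)
  time <- rexp(50, 0.1); event <- rbinom(50, 1, 0.8); grp <- rbinom(50, 1, 0.5)
  f1 <- cox_fit(time, event, grp)
  f2 <- cox_fit(time, event, 1 - grp)
  expect_lt(abs(f1$beta + f2$beta), 1e-8)
  expect_lt(abs(f1$hr - 1 / f2$hr), 1e-8)
})

test_that("non-estimable fits are refused with explicit errors", {
  expect_error(cox_fit(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 0, 1, 1)),
               "no events")
  # all events in one group: monotone likelihood
  expect_error(cox_fit(c(1, 2, 3, 4), c(1, 1, 0, 0), c(1, 1, 0, 0)),
               "not estimable")
  expect_error(cox_fit(c(1, 2), c(1, 1), c(2, 3)), "binary")
})

test_that("log-rank equals the Cox score test at beta 0 (no ties/censoring)", {
  set.seed(90)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1)             # continuous: no ties
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2) next
    lr <- logrank_test(time[grp == 0], rep(1, sum(grp == 0)),
                       time[grp == 1], rep(1, sum(grp == 1)))
    dv <- wsirisk:::cox_derivs(0, time, rep(1, n), grp)
    # score statistic U(0)^2 / I(0); identical to log-rank without ties
    expect_lt(abs(lr$statistic - dv$score^2 / dv$info), 1e-8)
  }
})

test_that("survival_report stratifies predicted groups end to end", {
  set.seed(41)
  n <- 300
  grp <- rep(c("predicted_low", "predicted_high"), each = n / 2)
  lam <- ifelse(grp == "predicted_high", 0.03, 0.01)
  tt <- rexp(n, lam); cc <- runif(n, 0, 120)
  rec <- data.frame(patient_id = sprintf("P%03d", 1:n),
                    time_months = pmin(tt, cc), event = as.integer(tt <= cc),
                    group = grp)
  rep_ <- survival_report(rec)
  expect_s3_class(rep_$cox, "wsi_cox")
  expect_gt(rep_$cox$hr, 1)
  expect_lt(rep_$logrank$p_value, 0.05)
  expect_true(rep_$median_high <= rep_$median_low)
})
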