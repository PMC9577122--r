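# Survival stratification: product-limit (Kaplan-Meier) estimation, the
# two-group log-rank test, and univariate Cox proportional-hazards fitting
# by Newton iteration on the partial likelihood (Breslow tie handling by
# default, Efron available).  These are authored implementations; the
# test-suite cross-checks them against the survival package and against
# brute-force oracles.

check_surv_input <- function(time, event) {
  assert_that(length(time) == length(event) && length(time) >= 1,
              "time and event must be nonempty and of equal length")
  assert_that(all(is.finite(time)) && all(time > 0),
              "all survival times must be positive")
  assert_that(all(event %in% c(0, 1)), "event indicators must be 0 or 1")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times (months).
#' @param event 1 = death, 0 = censored.
#' @param horizon Optional truncation horizon: records are censored at the
#'   horizon and event times beyond it are dropped.
#' @return A `wsi_km` object: data.frame `curve` with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `n_censor`, `surv`;
#'   plus `n` and `horizon`.  `S(0) = 1` is implicit; with no events the
#'   curve is empty and `S` is identically 1.
#' @export
km_estimate <- function(time, event, horizon = NULL) {
  check_surv_input(time, event)
  if (!is.null(horizon)) {
    event <- ifelse(time > horizon, 0L, event)
    time <- pmin(time, horizon)
  }
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(curve = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 n = n, horizon = horizon, max_follow_up = max(time)),
            class = "wsi_km")
}

#' Evaluate a Kaplan-Meier step function
#' @param km A `wsi_km`.
#' @param t Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$curve$time <= tt)
    if (i == 0) 1 else km$curve$surv[i]
  }, numeric(1))
}

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below; `Inf` ("not reached") when S stays above 0.5 throughout follow-up.
#'
#' @param km A `wsi_km`.
#' @return Months, or `Inf` when the median is not reached.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "wsi_km"))
  i <- which(km$curve$surv <= 0.5 + 1e-12)
  if (length(i) == 0) Inf else km$curve$time[min(i)]
}

#' Two-group log-rank test
#'
#' Pooled-risk-set observed-minus-expected events with the hypergeometric
#' variance; the statistic is chi-squared with 1 df under the null.
#'
#' @param time1,event1 Follow-up for group 1 (e.g. predicted low risk).
#' @param time2,event2 Follow-up for group 2.
#' @param horizon Optional truncation horizon applied to both groups.
#' @return List with `statistic`, `p_value`, `observed` and `expected`
#'   events per group.  With zero pooled events: statistic 0, p 1, and a
#'   warning.
#' @export
logrank_test <- function(time1, event1, time2, event2, horizon = NULL) {
  check_surv_input(time1, event1)
  check_surv_input(time2, event2)
  if (!is.null(horizon)) {
    event1 <- ifelse(time1 > horizon, 0L, event1); time1 <- pmin(time1, horizon)
    event2 <- ifelse(time2 > horizon, 0L, event2); time2 <- pmin(time2, horizon)
  }
  time <- c(time1, time2); event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  # risk-set sizes via sorted suffix counts: n at risk at t = #{time >= t}
  ts <- sort(time)
  ts1 <- sort(time[grp == 1])
  n_at <- length(ts) - findInterval(ut, ts, left.open = TRUE)
  n1_at <- length(ts1) - findInterval(ut, ts1, left.open = TRUE)
  d_at <- as.numeric(tabulate(match(time[event == 1], ut), length(ut)))
  d1_at <- as.numeric(tabulate(match(time[event == 1 & grp == 1], ut), length(ut)))
  o1 <- sum(d1_at)
  e1 <- sum(d_at * n1_at / n_at)
  ok <- n_at > 1
  v <- sum((d_at * (n1_at / n_at) * (1 - n1_at / n_at) *
            (n_at - d_at) / (n_at - 1))[ok])
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  d_tot <- sum(event)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(o1, d_tot - o1), expected = c(e1, d_tot - e1))
}

# Partial log-likelihood, score and information for a single numeric
# covariate, Breslow or Efron tie handling.  Risk-set sums are suffix
# cumulative sums over the time-sorted records, so a fit is O(n log n).
cox_derivs <- function(beta, time, event, x, ties = "breslow") {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  ebx <- exp(beta * x_s)
  suf <- function(v) rev(cumsum(rev(v)))
  s0suf <- suf(ebx); s1suf <- suf(x_s * ebx); s2suf <- suf(x_s^2 * ebx)
  ut <- unique(t_s[e_s == 1])
  idx <- findInterval(ut, t_s, left.open = TRUE) + 1L  # first j: t_s[j] >= ut
  s0 <- s0suf[idx]; s1 <- s1suf[idx]; s2 <- s2suf[idx]
  # per-event-time tallies over the event records
  et <- t_s[e_s == 1]; ex <- x_s[e_s == 1]; eebx <- ebx[e_s == 1]
  key <- match(et, ut)
  d <- as.numeric(tabulate(key, length(ut)))
  xs <- as.numeric(rowsum(ex, key, reorder = TRUE)[, 1])
  ll <- U <- I <- 0
  if (ties == "breslow") {
    ll <- sum(beta * xs - d * log(s0))
    U <- sum(xs - d * s1 / s0)
    I <- sum(d * (s2 / s0 - (s1 / s0)^2))
  } else {  # Efron
    t0 <- as.numeric(rowsum(eebx, key, reorder = TRUE)[, 1])
    t1 <- as.numeric(rowsum(ex * eebx, key, reorder = TRUE)[, 1])
    t2 <- as.numeric(rowsum(ex^2 * eebx, key, reorder = TRUE)[, 1])
    ll <- sum(beta * xs)
    U <- sum(xs)
    for (j in seq_along(ut)) {
      k <- 0:(d[j] - 1)
      a0 <- s0[j] - k / d[j] * t0[j]
      a1 <- s1[j] - k / d[j] * t1[j]
      a2 <- s2[j] - k / d[j] * t2[j]
      ll <- ll - sum(log(a0))
      U <- U - sum(a1 / a0)
      I <- I + sum(a2 / a0 - (a1 / a0)^2)
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Univariate Cox proportional-hazards fit for a binary risk group
#'
#' Maximizes the partial likelihood (Breslow tie handling by default) by
#' Newton iteration to `|delta beta| < 1e-8`.  The Wald 95 percent CI is
#' `exp(beta +- 1.96 se)`.  The fit refuses (errors) when there are no
#' events, or when either group has zero events (monotone likelihood, the
#' hazard ratio is not estimable).
#'
#' @param time Positive follow-up times (months).
#' @param event 1 = death, 0 = censored.
#' @param group Binary covariate: 1/`"high_risk"` vs 0/`"low_risk"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param horizon Optional truncation horizon.
#' @return A `wsi_cox` list: `beta`, `se`, `hr`, `ci` (length 2),
#'   `p_value`, `n`, `n_events`, `ties`.
#' @export
cox_fit <- function(time, event, group, ties = c("breslow", "efron"),
                    horizon = NULL) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  if (is.character(group) || is.factor(group))
    group <- as.integer(as.character(group) == "high_risk")
  assert_that(all(group %in% c(0, 1)), "group must be binary (0/1 or risk labels)")
  assert_that(length(group) == length(time), "group length mismatch")
  if (!is.null(horizon)) {
    event <- ifelse(time > horizon, 0L, event)
    time <- pmin(time, horizon)
  }
  d_tot <- sum(event)
  if (d_tot == 0)
    stop("no events: hazard ratio is not estimable", call. = FALSE)
  d1 <- sum(event[group == 1]); d0 <- d_tot - d1
  if (d1 == 0 || d0 == 0)
    stop("one group has zero events: hazard ratio is not estimable (monotone likelihood)",
         call. = FALSE)
  beta <- 0
  for (it in 1:100) {
    dv <- cox_derivs(beta, time, event, group, ties)
    # divergence: quasi-complete separation in event ordering also makes
    # the partial likelihood monotone even when both groups have events
    if (dv$info <= 1e-10 || abs(beta) > 15)
      stop("hazard ratio is not estimable (monotone partial likelihood)",
           call. = FALSE)
    step <- dv$score / dv$info
    step <- max(min(step, 2), -2)  # damp wild early steps
    beta <- beta + step
    if (abs(step) < 1e-8) break
  }
  dv <- cox_derivs(beta, time, event, group, ties)
  se <- 1 / sqrt(dv$info)
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * 1.96 * se),
                 p_value = 2 * pnorm(-abs(z)),
                 loglik = dv$loglik, score_at_solution = dv$score,
                 n = length(time), n_events = d_tot, ties = ties),
            class = "wsi_cox")
}

#' Survival stratification report for predicted risk groups
#'
#' Runs Kaplan-Meier per predicted group, the log-rank test and (when
#' estimable) the univariate Cox fit.
#'
#' @param records data.frame with `time_months`, `event` and `group`
#'   (`"predicted_low"`/`"predicted_high"` or risk labels).
#' @param horizon Optional truncation (months).
#' @return List with `km_low`, `km_high`, `median_low`, `median_high`,
#'   `logrank` and `cox` (the latter may be a string explaining
#'   non-estimability).
#' @export
survival_report <- function(records, horizon = NULL) {
  assert_that(all(c("time_months", "event", "group") %in% names(records)),
              "records must have time_months, event, group")
  g <- as.character(records$group)
  high <- g %in% c("high_risk", "predicted_high", "1")
  assert_that(any(high) && !all(high), "both predicted groups must be nonempty")
  tl <- records$time_months[!high]; el <- records$event[!high]
  th <- records$time_months[high]; eh <- records$event[high]
  km_low <- km_estimate(tl, el, horizon)
  km_high <- km_estimate(th, eh, horizon)
  lr <- logrank_test(tl, el, th, eh, horizon)
  cox <- tryCatch(cox_fit(records$time_months, records$event, as.integer(high),
                          horizon = horizon),
                  error = function(e) conditionMessage(e))
  list(km_low = km_low, km_high = km_high,
       median_low = median_survival(km_low), median_high = median_survival(km_high),
       logrank = lr, cox = cox)
}
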