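# Confusion matrices, metrics, bootstrap CIs.

test_that("confusion matrices tally exactly with fixed ordering", {
  t4 <- c("low_risk", "low_risk", "high_risk", "high_risk")
  p4 <- c("low_risk", "high_risk", "high_risk", "high_risk")
  cm <- confusion_matrix(t4, p4)
  expect_identical(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_identical(rownames(cm), c("low_risk", "high_risk"))

  perfect <- confusion_matrix(rep(c("low_risk", "high_risk"), c(6, 4)),
                              rep(c("low_risk", "high_risk"), c(6, 4)))
  expect_identical(unname(diag(perfect)), c(6L, 4L))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)

  expect_warning(z <- confusion_matrix(character(0), character(0)), "empty")
  expect_identical(sum(z), 0L)
  expect_error(confusion_matrix(c("low_risk"), c("low_risk", "high_risk")),
               "equal length")
  expect_error(confusion_matrix("benign", "low_risk"), "labels")
})

test_that("metrics reproduce hand arithmetic and conventions", {
  cm <- matrix(c(50L, 5L, 10L, 35L), 2,
               dimnames = list(truth = wsi_risk_levels(),
                               prediction = wsi_risk_levels()))
  m <- classification_metrics(cm)
  p_low <- 50 / 55; r_low <- 50 / 60
  expect_equal(m$per_class$precision[1], p_low)
  expect_equal(m$per_class$recall[1], r_low)
  expect_equal(m$per_class$f1[1], 2 * p_low * r_low / (p_low + r_low))
  expect_equal(m$accuracy, 85 / 100)

  perfect <- classification_metrics(matrix(c(7L, 0L, 0L, 3L), 2))
  expect_true(all(perfect$per_class[, c("precision", "recall", "f1")] == 1))
  expect_identical(unname(perfect$weighted), c(1, 1, 1))

  # zero-support class is flagged and excluded from the weighted average
  zs <- classification_metrics(matrix(c(8L, 0L, 2L, 0L), 2))
  expect_true(zs$per_class$flagged[2])
  expect_equal(unname(zs$weighted["recall"]), 0.8)
})

test_that("weighted recall equals accuracy on random 2x2 confusions", {
  set.seed(19)
  for (i in 1:50) {
    cm <- matrix(as.integer(rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1))), 2)
    if (any(rowSums(cm) == 0)) next
    m <- classification_metrics(cm)
    expect_equal(unname(m$weighted["recall"]), m$accuracy, tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are seeded, degenerate-safe and honest about skips", {
  truths <- rep(c("low_risk", "high_risk"), c(12, 8))
  ci1 <- bootstrap_ci(truths, truths, "weighted_f1", iterations = 200, seed = 6)
  expect_identical(as.numeric(ci1), c(1, 1))  # perfect prediction: point mass
  preds <- replace(truths, c(1, 15), c("high_risk", "low_risk"))
  ci2 <- bootstrap_ci(truths, preds, "weighted_f1", iterations = 500, seed = 6)
  ci3 <- bootstrap_ci(truths, preds, "weighted_f1", iterations = 500, seed = 6)
  expect_identical(ci2, ci3)
  expect_true(ci2[1] <= attr(ci2, "point") && attr(ci2, "point") <= ci2[2])
  # custom metric returning NA in some replicates is skipped and counted
  flaky <- function(t, p) if (sum(t == "high_risk") < 6) NA_real_ else mean(t == p)
  ci4 <- bootstrap_ci(truths, preds, flaky, iterations = 300, seed = 2)
  expect_gt(attr(ci4, "n_skipped"), 0)
})

test_that("CI width shrinks with sample size at fixed accuracy", {
  wider <- 0
  for (s in 1:20) {
    make <- function(n) {
      set.seed(s)
      t <- rep(c("low_risk", "high_risk"), length.out = n)
      p <- ifelse(runif(n) < 0.85, t,
                  ifelse(t == "low_risk", "high_risk", "low_risk"))
      bootstrap_ci(t, p, "accuracy", iterations = 300, seed = s)
    }
    w50 <- diff(make(50)); w500 <- diff(make(500))
    if (w500 >= w50) wider <- wider + 1
  }
  expect_lte(wider, 2)  # stochastic dominance, allow rare inversions
})

test_that("metrics_report assembles per-metric CIs", {
  truths <- rep(c("low_risk", "high_risk"), c(30, 20))
  set.seed(1)
  preds <- ifelse(runif(50) < 0.9, truths,
                  ifelse(truths == "low_risk", "high_risk", "low_risk"))
  m <- metrics_report(truths, preds, iterations = 200, seed = 8)
  expect_named(m$ci, c("accuracy", "weighted_precision", "weighted_recall",
                       "weighted_f1", "precision_low", "recall_low", "f1_low",
                       "precision_high", "recall_high", "f1_high"))
  for (ci in m$ci) expect_true(ci[1] <= ci[2])
})
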