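# Classification metrics with bootstrap confidence intervals.
#
# Metrics follow the usual one-vs-rest definitions on the 2x2 risk
# confusion matrix (rows = truth, columns = prediction, order low/high);
# "weighted" averages weight each class by its true support.  Confidence
# intervals are percentile bootstrap over slides (or patients), 10 000
# replicates by default.

#' Confusion matrix over risk labels
#'
#' @param truths,predictions Equal-length vectors over
#'   `c("low_risk", "high_risk")`.
#' @return 2x2 integer matrix, rows = truth, cols = prediction, order
#'   (low, high).  Empty input gives an all-zero matrix with a warning.
#' @export
confusion_matrix <- function(truths, predictions) {
  lv <- wsi_risk_levels()
  assert_that(length(truths) == length(predictions),
              "truths and predictions must have equal length")
  if (length(truths) == 0) {
    warning("empty input; returning an all-zero confusion matrix")
    m <- matrix(0L, 2, 2, dimnames = list(truth = lv, prediction = lv))
    return(m)
  }
  assert_that(all(truths %in% lv) && all(predictions %in% lv),
              "labels must be 'low_risk' or 'high_risk'")
  m <- table(factor(truths, levels = lv), factor(predictions, levels = lv))
  m <- matrix(as.integer(m), 2, 2, dimnames = list(truth = lv, prediction = lv))
  m
}

#' Per-class and weighted classification metrics
#'
#' Precision, recall and F1 per class (one-vs-rest on the 2x2 matrix),
#' overall accuracy, and support-weighted averages.  A metric with a zero
#' denominator is reported as 0 and flagged; a class with zero support is
#' flagged and excluded from the weighted averages.
#'
#' @param confusion 2x2 matrix from [confusion_matrix()].
#' @return A `wsi_metrics` list: `per_class` data.frame (`class`,
#'   `support`, `precision`, `recall`, `f1`, `flagged`), `accuracy`, and
#'   `weighted` (named vector: precision, recall, f1).
#' @export
classification_metrics <- function(confusion) {
  assert_that(is.matrix(confusion) && all(dim(confusion) == c(2, 2)),
              "expected a 2x2 confusion matrix")
  n <- sum(confusion)
  assert_that(n > 0, "empty confusion matrix")
  lv <- wsi_risk_levels()
  support <- rowSums(confusion)
  res <- data.frame(class = lv, support = as.numeric(support),
                    precision = 0, recall = 0, f1 = 0, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in 1:2) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    prec <- if (tp + fp > 0) tp / (tp + fp) else { res$flagged[i] <- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { res$flagged[i] <- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    res$precision[i] <- prec; res$recall[i] <- rec; res$f1[i] <- f1
    if (support[i] == 0) res$flagged[i] <- TRUE
  }
  keep <- support > 0
  w <- support[keep] / sum(support[keep])
  weighted <- c(precision = sum(w * res$precision[keep]),
                recall = sum(w * res$recall[keep]),
                f1 = sum(w * res$f1[keep]))
  structure(list(confusion = confusion, per_class = res,
                 accuracy = sum(diag(confusion)) / n, weighted = weighted),
            class = "wsi_metrics")
}

metric_value <- function(truths, predictions, metric) {
  if (is.function(metric)) return(metric(truths, predictions))
  cm <- suppressWarnings(confusion_matrix(truths, predictions))
  if (sum(cm) == 0) return(NA_real_)
  m <- classification_metrics(cm)
  switch(metric,
         accuracy = m$accuracy,
         weighted_precision = unname(m$weighted["precision"]),
         weighted_recall = unname(m$weighted["recall"]),
         weighted_f1 = unname(m$weighted["f1"]),
         precision_low = m$per_class$precision[1],
         precision_high = m$per_class$precision[2],
         recall_low = m$per_class$recall[1],
         recall_high = m$per_class$recall[2],
         f1_low = m$per_class$f1[1],
         f1_high = m$per_class$f1[2],
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples the evaluation units (slides or patients) with replacement,
#' n-out-of-n, recomputes the metric per replicate, and reports the 2.5th
#' and 97.5th percentiles.  Replicates where the metric is undefined are
#' skipped and counted.
#'
#' @param truths,predictions Risk-label vectors (length at least 2).
#' @param metric Metric name (e.g. `"weighted_f1"`, `"accuracy"`) or a
#'   function `(truths, predictions) -> number`.
#' @param iterations Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)` with attributes `point` (full-sample
#'   value) and `n_skipped`.
#' @export
bootstrap_ci <- function(truths, predictions, metric = "weighted_f1",
                         iterations = 10000L, seed = 1L) {
  n <- length(truths)
  assert_that(n >= 2, "need at least 2 units to bootstrap")
  assert_that(iterations >= 1, "iterations must be at least 1")
  vals <- with_seed(seed, {
    vapply(seq_len(iterations), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_value(truths[idx], predictions[idx], metric)
    }, numeric(1))
  })
  skipped <- sum(!is.finite(vals))
  vals <- vals[is.finite(vals)]
  assert_that(length(vals) > 0, "metric undefined in every bootstrap replicate")
  ci <- unname(quantile(vals, c(0.025, 0.975), type = 7))
  attr(ci, "point") <- metric_value(truths, predictions, metric)
  attr(ci, "n_skipped") <- skipped
  ci
}

#' Full metrics report with bootstrap CIs
#'
#' @param truths,predictions Risk-label vectors.
#' @param iterations Bootstrap replicates per metric (default 10000).
#' @param seed Integer seed.
#' @return A `wsi_metrics` with an added `ci` element: a named list of
#'   `c(lower, upper)` per metric.
#' @export
metrics_report <- function(truths, predictions, iterations = 10000L, seed = 1L) {
  m <- classification_metrics(confusion_matrix(truths, predictions))
  metrics <- c("accuracy", "weighted_precision", "weighted_recall", "weighted_f1",
               "precision_low", "recall_low", "f1_low",
               "precision_high", "recall_high", "f1_high")
  m$ci <- lapply(stats::setNames(metrics, metrics), function(mt)
    bootstrap_ci(truths, predictions, mt, iterations,
                 seed = substream_seed(seed, mt)))
  m
}
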