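# Confidence-based fusion of the four binary patch labels.
#
# A patch is kept only when exactly one of the four one-vs-rest classifiers
# fires: it then resolves to that class.  A patch with zero firing
# classifiers ("others" everywhere: normal or unrecognized tissue) or two
# or more firing classifiers (conflicting evidence) is eliminated from
# slide inference.  No threshold beyond the per-classifier binarization is
# involved.

#' Resolve a four-label patch combination to its fate
#'
#' Total pure function on all 16 combinations: exactly the four one-hot
#' inputs resolve (to their class); everything else is eliminated.
#'
#' @param labels Logical or 0/1 vector of length 4 in [wsi_classes()] order.
#' @return List with `fate` (`"resolved"` or `"eliminated"`) and `class`
#'   (the class name, or `NA` when eliminated).
#' @export
resolve_patch_label <- function(labels) {
  assert_that(length(labels) == 4, "expected exactly four binary labels")
  l <- as.logical(labels)
  assert_that(!anyNA(l), "labels must be binary")
  if (sum(l) == 1L) list(fate = "resolved", class = wsi_classes()[which(l)])
  else list(fate = "eliminated", class = NA_character_)
}

#' Resolve a matrix of patch label sets
#' @param label_matrix n x 4 logical/0-1 matrix, columns in [wsi_classes()]
#'   order.
#' @return Character vector of fates: a class name or `"eliminated"`.
#' @export
resolve_patch_labels <- function(label_matrix) {
  assert_that(is.matrix(label_matrix) && ncol(label_matrix) == 4,
              "expected an n x 4 label matrix")
  m <- matrix(as.logical(label_matrix), ncol = 4)
  fired <- rowSums(m)
  out <- rep("eliminated", nrow(m))
  one <- fired == 1L
  out[one] <- wsi_classes()[max.col(m[one, , drop = FALSE])]
  out
}

#' Build the per-slide class-ratio vector from patch fates
#'
#' Each class ratio is the count of patches resolved to that class over the
#' denominator; by default the denominator is all tissue patches submitted
#' to classification (eliminated patches count in the denominator only),
#' giving conservative ratios.  The combined low-risk ratio is
#' `r_PUNLMP + r_low_grade`; the high-risk ratio is
#' `r_high_grade + r_invasive`.
#'
#' @param fates Character vector from [resolve_patch_labels()] (class names
#'   and `"eliminated"`).
#' @param denominator_mode `"all"` (default) or `"resolved"`.
#' @return A `wsi_ratio` list: `ratios` (named length-4 vector),
#'   `low_risk_ratio`, `high_risk_ratio`, `n_patches`, `n_eliminated`.
#' @export
compute_ratio_vector <- function(fates, denominator_mode = c("all", "resolved")) {
  denominator_mode <- match.arg(denominator_mode)
  n <- length(fates)
  if (n == 0) stop("unclassifiable slide: no patches entered classification", call. = FALSE)
  assert_that(all(fates %in% c(wsi_classes(), "eliminated")),
              "fates must be class names or 'eliminated'")
  counts <- vapply(wsi_classes(), function(cl) sum(fates == cl), integer(1))
  n_elim <- sum(fates == "eliminated")
  denom <- if (denominator_mode == "all") n else n - n_elim
  if (denom == 0)
    stop("unclassifiable slide: every patch was eliminated", call. = FALSE)
  ratios <- counts / denom
  structure(list(ratios = ratios,
                 low_risk_ratio = unname(ratios["PUNLMP"] + ratios["low_grade"]),
                 high_risk_ratio = unname(ratios["high_grade"] + ratios["invasive"]),
                 n_patches = n, n_eliminated = n_elim,
                 denominator_mode = denominator_mode),
            class = "wsi_ratio")
}

#' Ratio features for the slide classifier
#' @param ratio A `wsi_ratio` or list of them.
#' @param feature_mode `"combined"` (2-vector: low/high-risk ratios,
#'   default) or `"per_class"` (the four class ratios).
#' @return Numeric matrix, one row per slide.
#' @export
ratio_features <- function(ratio, feature_mode = c("combined", "per_class")) {
  feature_mode <- match.arg(feature_mode)
  if (inherits(ratio, "wsi_ratio")) ratio <- list(ratio)
  t(vapply(ratio, function(r) {
    if (feature_mode == "combined") c(low = r$low_risk_ratio, high = r$high_risk_ratio)
    else r$ratios
  }, numeric(if (feature_mode == "combined") 2 else 4)))
}
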