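#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) formulation with midranks for ties:
#' the probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  assert_that(length(unique(labels)) == 2 && all(labels %in% c(0, 1)),
              "both classes required for AUROC",
              class = "odynr_validation_error")
  r <- midrank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve: thresholds sweep the
#' unique scores descending and the curve is integrated as
#' `sum(precision_i * delta_recall_i)` (average-precision convention).
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  assert_that(length(unique(labels)) == 2 && all(labels %in% c(0, 1)),
              "both classes required for AUPRC",
              class = "odynr_validation_error")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Pixel-level segmentation mask metrics
#'
#' F1 (Dice), recall and precision of a predicted binary mask against a
#' ground-truth mask, aggregated over all pixels of the provided regions.
#'
#' @param pred,truth Co-registered [mask_raster()] objects.
#' @return One-row tibble: `f1`, `recall`, `precision`, pixel counts.
#' @export
mask_metrics <- function(pred, truth) {
  check_coregistered(pred, truth)
  tp <- sum(pred$pixels & truth$pixels)
  fp <- sum(pred$pixels & !truth$pixels)
  fn <- sum(!pred$pixels & truth$pixels)
  tibble::tibble(
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}

#' Specificity of a mask against an all-negative truth
#'
#' For control slides whose ground truth contains no positive pixels, F1,
#' recall and precision degenerate; the reported measure is specificity,
#' `TN / (TN + FP)`.
#'
#' @param pred Predicted [mask_raster()].
#' @return Specificity in `[0, 1]`.
#' @export
mask_specificity <- function(pred) {
  n <- length(pred$pixels)
  fp <- sum(pred$pixels)
  (n - fp) / n
}
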