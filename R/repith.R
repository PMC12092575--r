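#' Dysplasia-epithelium ratio of a slide
#'
#' R_Epith is the proportion of the epithelium mask that is also segmented
#' as dysplastic: the numerator counts pixels positive in both masks
#' (dysplasia is intersected with the epithelium before division, the only
#' reading that guarantees a ratio in `[0, 1]`). Slides with no epithelium
#' pixels have an undefined ratio and are flagged `no_epithelium` rather
#' than assigned 0.
#'
#' @param epithelium,dysplasia Co-registered [mask_raster()] objects.
#' @return One-row tibble: `slide_id`, `r_epith`, `epithelium_pixels`,
#'   `dysplastic_pixels`, `no_epithelium`.
#' @export
compute_repith <- function(epithelium, dysplasia) {
  check_coregistered(epithelium, dysplasia)
  ep <- sum(epithelium$pixels)
  dy <- sum(epithelium$pixels & dysplasia$pixels)
  tibble::tibble(
    slide_id = epithelium$slide_id,
    r_epith = if (ep > 0) dy / ep else NA_real_,
    epithelium_pixels = ep,
    dysplastic_pixels = dy,
    no_epithelium = ep == 0
  )
}

f1_binary <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Select the R_Epith classification threshold on a training set
#'
#' Candidate cut points are the midpoints between consecutive sorted unique
#' ratios plus `{0, 1}`; the returned threshold maximises the F1-score of
#' the dysplastic class (slides classified dysplastic when
#' `r_epith >= threshold`), with ties broken towards the smaller threshold.
#' The training AUROC of the raw ratios is reported alongside.
#'
#' @param ratios Per-slide R_Epith values.
#' @param labels Binary slide labels (1 = dysplastic/OED, 0 = control).
#' @return A `repith_threshold` model object.
#' @export
select_threshold <- function(ratios, labels) {
  keep <- !is.na(ratios)
  ratios <- ratios[keep]; labels <- labels[keep]
  assert_that(length(unique(labels)) == 2,
              "both classes required to select a threshold",
              class = "odynr_validation_error")
  u <- sort(unique(ratios))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  f1s <- vapply(cand, function(th) f1_binary(as.integer(ratios >= th), labels),
                numeric(1))
  best <- cand[which.max(f1s)]  # which.max takes the first (smallest) on ties
  structure(
    list(threshold = best,
         training_f1 = max(f1s),
         training_auroc = auroc(ratios, labels),
         n_training_slides = length(ratios),
         candidates = cand),
    class = "repith_threshold"
  )
}

#' @export
print.repith_threshold <- function(x, ...) {
  cat(sprintf("<repith_threshold> t=%.4g (training F1=%.3f, AUROC=%.3f, n=%d)\n",
              x$threshold, x$training_f1, x$training_auroc,
              x$n_training_slides))
  invisible(x)
}

#' @export
tidy.repith_threshold <- function(x, ...) {
  tibble::tibble(term = "threshold", estimate = x$threshold)
}

#' @export
glance.repith_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, training_f1 = x$training_f1,
                 training_auroc = x$training_auroc,
                 n_training_slides = x$n_training_slides)
}

#' Classify slides as dysplastic vs non-dysplastic
#'
#' Applies the fitted threshold to per-slide R_Epith results with the
#' inclusive rule: dysplastic iff `r_epith >= threshold`. Slides flagged
#' `no_epithelium` are unclassifiable (`NA` label) and must be excluded from
#' downstream metrics with a logged count.
#'
#' @param repith Tibble from [compute_repith()] (one or more rows).
#' @param model A [select_threshold()] fit.
#' @return Input tibble with a `classification` column
#'   (`"dysplastic"`/`"non_dysplastic"`/`NA`).
#' @export
classify_slides <- function(repith, model) {
  stopifnot(inherits(model, "repith_threshold"))
  lab <- ifelse(repith$no_epithelium, NA_character_,
                ifelse(repith$r_epith >= model$threshold,
                       "dysplastic", "non_dysplastic"))
  drop_log(sum(is.na(lab)), "unclassifiable slides (no epithelium)")
  dplyr::mutate(repith, classification = lab)
}
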