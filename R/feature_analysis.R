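TOP_TILE_MEASURES <- c(
  count_dysplastic_epithelial = "dysplastic_epithelial_count",
  count_normal_epithelial = "normal_epithelial_count",
  count_iel = "iel_count",
  count_pel = "pel_count",
  area_other_tissue = "tissue_frac_other",
  area_dysplastic_epith = "tissue_frac_dysplastic_epith",
  area_normal_epith = "tissue_frac_normal_epith"
)

#' Nuclear count and area-ratio analysis of the top-ranked tiles
#'
#' Compares the tiles driving the risk score between slides the model got
#' right in each direction: true positives (predicted high risk and
#' transformed) versus true negatives (predicted low risk, no
#' transformation). For each such slide the `n_tiles` highest-scoring
#' patches are pooled, and seven per-patch measures are compared across the
#' two groups: counts of dysplastic epithelial, normal epithelial, IEL and
#' PEL nuclei, and area ratios of other tissue, dysplastic epithelium and
#' normal epithelium (the three ratios partition each patch). Each measure
#' is gated by a Shapiro-Wilk normality check, compared by a two-tailed
#' Mann-Whitney U test with rank-biserial effect size, and the p-values are
#' BH-FDR adjusted across the measure family. Medians and IQRs are reported
#' per group.
#'
#' @param patch_scores Tibble `slide_id`, `patch_id`, `score` (per-patch
#'   positive-class probabilities; e.g. from [predict_patches()]).
#' @param features Feature tibble from [extract_features()] covering the
#'   same patches.
#' @param predictions Tibble `slide_id`, `risk_group` (`"high"`/`"low"`).
#' @param cohort Cohort tibble with the true `transformed` status.
#' @param n_tiles Tiles per slide (default 10).
#' @return Tibble: one row per measure with test statistics, adjusted
#'   p-values, effect sizes and per-group descriptives.
#' @export
top_tile_feature_analysis <- function(patch_scores, features, predictions,
                                      cohort, n_tiles = 10L) {
  truth <- stats::setNames(cohort$transformed, cohort$slide_id)
  pred <- predictions |>
    dplyr::mutate(transformed = truth[.data$slide_id],
                  status = dplyr::case_when(
                    .data$risk_group == "high" & .data$transformed == 1 ~ "TP",
                    .data$risk_group == "low" & .data$transformed == 0 ~ "TN",
                    TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$status))
  assert_that(all(c("TP", "TN") %in% pred$status),
              "need at least one true-positive and one true-negative slide",
              class = "odynr_validation_error")

  top <- patch_scores |>
    dplyr::inner_join(pred[, c("slide_id", "status")], by = "slide_id") |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::slice_max(.data$score, n = n_tiles, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::inner_join(features, by = c("slide_id", "patch_id"))

  rows <- purrr::imap(TOP_TILE_MEASURES, function(col, label) {
    x <- top[[col]][top$status == "TP"]
    y <- top[[col]][top$status == "TN"]
    sw_p <- tryCatch(shapiro_wilk(c(x, y))$p_value, error = function(e) NA_real_)
    mw <- mann_whitney_rrb(x, y)
    tibble::tibble(
      measure = label, shapiro_p = sw_p, u = mw$u, p_value = mw$p_value,
      r_rb = mw$r_rb, n_tp = mw$n_x, n_tn = mw$n_y,
      median_tp = mw$median_x, iqr_tp_lo = mw$iqr_x_lo, iqr_tp_hi = mw$iqr_x_hi,
      median_tn = mw$median_y, iqr_tn_lo = mw$iqr_y_lo, iqr_tn_hi = mw$iqr_y_hi
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_fdr(out$p_value)
  dplyr::relocate(out, "p_adj", .after = "p_value")
}
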