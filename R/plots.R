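#' Boxplots of the dysplasia-epithelium ratio by a clinical grouping
#'
#' @param repith R_Epith tibble ([compute_repith()] rows).
#' @param cohort Cohort tibble.
#' @param by Grouping column of the cohort (e.g. `"transformed"`,
#'   `"binary_grade"`, `"who_grade"`).
#' @return A ggplot object.
#' @export
plot_repith_distribution <- function(repith, cohort, by = "transformed") {
  df <- dplyr::inner_join(repith, cohort, by = "slide_id") |>
    dplyr::filter(!is.na(.data[[by]]), !.data$no_epithelium)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[by]]),
                                   y = .data$r_epith,
                                   fill = factor(.data[[by]]))) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = 1) +
    ggplot2::labs(x = by, y = "dysplasia-epithelium ratio") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier transformation-free survival plot
#'
#' @param km A [km_logrank()] result.
#' @return A ggplot object (step curves with censor marks).
#' @export
plot_km <- function(km) {
  cv <- km$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(tibble::tibble(time = 0, n_risk = max(df$n_risk),
                                      n_event = 0L, n_censor = 0L,
                                      survival = 1), df)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cv[cv$n_censor > 0, ], shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "transformation-free survival",
                  subtitle = sprintf("log-rank p = %.3g", km$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.odyn_cv <- function(object, cohort = NULL, ...) {
  df <- object$mean_scores
  if (!is.null(cohort)) {
    df$transformed <- cohort$transformed[match(df$slide_id, cohort$slide_id)]
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$transformed),
                                     y = .data$odyn_score)) +
      ggplot2::geom_boxplot(alpha = 0.7) +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
      ggplot2::labs(x = "transformed", y = "risk score (mean out-of-fold)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$odyn_score)) +
      ggplot2::geom_histogram(bins = 20) +
      ggplot2::labs(x = "risk score") +
      ggplot2::theme_minimal()
  }
}

#' Patch-score heatmap of one slide
#'
#' @param patch_scores Tibble `patch_id`, `x`, `y`, `score` for one slide.
#' @param patch_size Patch side (target-mpp pixels).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(patch_scores, patch_size = 512) {
  ggplot2::ggplot(patch_scores,
                  ggplot2::aes(xmin = .data$x, xmax = .data$x + patch_size,
                               ymin = .data$y, ymax = .data$y + patch_size,
                               fill = .data$score)) +
    ggplot2::geom_rect(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "score") +
    ggplot2::theme_minimal()
}
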