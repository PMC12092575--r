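default_config <- function() {
  list(
    synth = list(n_patients = 20, slides_per_patient = 1, n_controls = 5,
                 canvas_size = 768, mask_mpp = 0.5, transform_fraction = 0.4,
                 nuclear_effect = 1, censor_rate = 0.1, seed = 1),
    grid = list(patch_size = 512, overlap = 256, target_mpp = 0.5,
                min_coverage = 0.1),
    train = list(k = 5, r = 45, batch_size = 256, lr = 1e-3, epochs = 30,
                 sce_alpha = 1, sce_beta = 1, log_clamp = -4,
                 weight_decay = 0, seed = 1),
    cv = list(n_folds = 5, n_repeats = 3, val_frac = 0.1, seed = 1),
    evaluate = list(cutoff = 0.5, horizon_months = 96, n_top_tiles = 10)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), merges it over the schema defaults
#' — which encode the standard settings: 512 px patches, 256 px overlap at
#' 0.5 mpp, `k = 5`, `r = 45`, batch 256, dropout 0.2, 96-month censor — and
#' validates every key, reporting all offending keys at once.
#'
#' @param path YAML file path, or `NULL`.
#' @param overrides Optional list merged over the file values.
#' @return Validated config list.
#' @export
odyn_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(user, overrides)) {
    for (sec in names(src)) {
      assert_that(sec %in% names(cfg),
                  sprintf("unknown config section `%s`", sec),
                  class = "odynr_validation_error")
      for (key in names(src[[sec]])) {
        assert_that(key %in% names(cfg[[sec]]),
                    sprintf("unknown config key `%s.%s`", sec, key),
                    class = "odynr_validation_error")
        cfg[[sec]][[key]] <- src[[sec]][[key]]
      }
    }
  }
  problems <- character(0)
  g <- cfg$grid
  if (g$overlap >= g$patch_size) {
    problems <- c(problems, "grid.overlap must be < grid.patch_size")
  }
  if (g$min_coverage < 0 || g$min_coverage > 1) {
    problems <- c(problems, "grid.min_coverage must be in [0, 1]")
  }
  if (cfg$cv$n_folds < 2) problems <- c(problems, "cv.n_folds must be >= 2")
  if (cfg$train$k + cfg$train$r < 1) {
    problems <- c(problems, "train.k + train.r must be >= 1")
  }
  if (cfg$evaluate$cutoff < 0 || cfg$evaluate$cutoff > 1) {
    problems <- c(problems, "evaluate.cutoff must be in [0, 1]")
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid configuration:", problems), collapse = "\n  "),
          class = "odynr_validation_error")
  }
  cfg
}

# Per-slide scoring-grid features for an in-memory slide bundle.
cohort_features <- function(slides, grid_cfg) {
  dropped <- character(0)
  feats <- list()
  for (sid in names(slides)) {
    sl <- slides[[sid]]
    grid <- make_patch_grid(dim(sl$epithelium), sl$epithelium$mpp,
                            patch_size = grid_cfg$patch_size,
                            overlap = grid_cfg$overlap,
                            target_mpp = grid_cfg$target_mpp)
    sg <- filter_scoring_patches(grid, sl$dysplasia,
                                 min_coverage = grid_cfg$min_coverage)
    if (nrow(sg) == 0) {
      dropped <- c(dropped, sid)
      next
    }
    feats[[sid]] <- extract_features(sl$epithelium, sl$dysplasia,
                                     sl$nuclei, sg)
  }
  out <- dplyr::bind_rows(feats)
  attr(out, "dropped_slides") <- dropped
  out
}

#' Evaluate a cross-validated scoring run
#'
#' Computes, per repeat and pooled: AUROC and AUPRC of the out-of-fold
#' scores against transformation; the C-index against transformation-free
#' survival (mean over repeats reported); Kaplan-Meier curves with the
#' log-rank test per repeat and the conservative p (twice the median over
#' repeats); and a multivariate Cox model of the risk group with age and
#' sex (plus site when present).
#'
#' @param cv An `odyn_cv` from [run_cv()].
#' @param cohort Cohort tibble.
#' @param cutoff Risk-group cutoff.
#' @param horizon_months Right-censoring horizon (default 96).
#' @param site_covariate Include `site` in the Cox model.
#' @return List: `metrics` (per-repeat + pooled tibble), `c_index_mean`,
#'   `km` (last repeat's curves), `logrank_ps`, `conservative_p`, `cox`.
#' @export
evaluate_scoring <- function(cv, cohort, cutoff = 0.5, horizon_months = 96,
                             site_covariate = FALSE) {
  truth <- stats::setNames(cohort$transformed, cohort$slide_id)
  per_repeat <- cv$scores |>
    dplyr::group_by(.data$repeat_i) |>
    dplyr::group_map(function(df, key) {
      y <- truth[df$slide_id]
      recs <- survival_records(cohort, df[, c("slide_id", "odyn_score")],
                               horizon_months = horizon_months)
      recs$risk_group <- ifelse(recs$odyn_score >= cutoff, "high", "low")
      lr_p <- if (length(unique(recs$risk_group)) == 2 && sum(recs$event) > 0) {
        km_logrank(recs, "risk_group")$p_value
      } else NA_real_
      tibble::tibble(
        repeat_i = key$repeat_i,
        auroc = auroc(df$odyn_score, y),
        auprc = auprc(df$odyn_score, y),
        c_index = concordance_index(recs$odyn_score, recs$time_months,
                                    recs$event),
        logrank_p = lr_p
      )
    }) |>
    dplyr::bind_rows()

  pooled_y <- truth[cv$mean_scores$slide_id]
  pooled <- tibble::tibble(
    repeat_i = NA_integer_,
    auroc = auroc(cv$mean_scores$odyn_score, pooled_y),
    auprc = auprc(cv$mean_scores$odyn_score, pooled_y),
    c_index = {
      recs <- survival_records(cohort,
                               cv$mean_scores[, c("slide_id", "odyn_score")],
                               horizon_months = horizon_months)
      concordance_index(recs$odyn_score, recs$time_months, recs$event)
    },
    logrank_p = NA_real_
  )

  recs <- survival_records(cohort,
                           cv$mean_scores[, c("slide_id", "odyn_score",
                                              "risk_group")],
                           horizon_months = horizon_months)
  km <- if (length(unique(recs$risk_group)) == 2 && sum(recs$event) > 0) {
    km_logrank(recs, "risk_group")
  } else NULL
  covars <- c("odyn_score", "age", "sex", if (site_covariate) "site")
  cox <- tryCatch(cox_multivariate(recs, covars), error = function(e) NULL)
  lr_ps <- per_repeat$logrank_p[!is.na(per_repeat$logrank_p)]
  list(
    metrics = dplyr::bind_rows(per_repeat, pooled),
    c_index_mean = mean(per_repeat$c_index),
    km = km,
    logrank_ps = lr_ps,
    conservative_p = if (length(lr_ps) > 0) conservative_p(lr_ps) else NA_real_,
    cox = cox
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates the stages end-to-end: generate (or accept) a cohort,
#' classify slides via the dysplasia-epithelium ratio when both dysplastic
#' and control slides are present, extract scoring-grid features inside the
#' dysplastic regions, train/score via repeated grouped cross-validation,
#' and evaluate. A run manifest (config snapshot, seeds, counts) is included
#' and, with `out_dir`, written to disk together with score and metric
#' artefacts.
#'
#' @param config A config list from [odyn_config()] (or a YAML path).
#' @param out_dir Optional artefact directory.
#' @param bundle Optional pre-generated [generate_cohort()] bundle (skips
#'   the synth stage).
#' @return List: `cohort`, `repith`, `threshold`, `features`, `cv`,
#'   `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config = odyn_config(), out_dir = NULL,
                         bundle = NULL) {
  if (is.character(config)) config <- odyn_config(config)
  sy <- config$synth
  if (is.null(bundle)) {
    bundle <- generate_cohort(synth_config(
      n_patients = sy$n_patients, slides_per_patient = sy$slides_per_patient,
      n_controls = sy$n_controls, canvas_size = sy$canvas_size,
      mask_mpp = sy$mask_mpp, transform_fraction = sy$transform_fraction,
      nuclear_effect = sy$nuclear_effect, censor_rate = sy$censor_rate,
      seed = sy$seed))
  }
  cohort <- bundle$cohort

  repith <- dplyr::bind_rows(lapply(bundle$slides, function(sl) {
    compute_repith(sl$epithelium, sl$dysplasia)
  }))
  threshold <- NULL
  if ("is_control" %in% names(cohort) && any(cohort$is_control) &&
      any(!cohort$is_control)) {
    lab <- as.integer(!cohort$is_control[match(repith$slide_id,
                                               cohort$slide_id)])
    threshold <- select_threshold(repith$r_epith, lab)
    repith <- classify_slides(repith, threshold)
  }

  oed_ids <- if ("is_control" %in% names(cohort)) {
    cohort$slide_id[!cohort$is_control]
  } else cohort$slide_id
  features <- cohort_features(bundle$slides[names(bundle$slides) %in% oed_ids],
                              config$grid)

  cv <- run_cv(cohort[cohort$slide_id %in% oed_ids, ], features,
               plan = cv_plan(config$cv$n_folds, config$cv$n_repeats,
                              config$cv$val_frac, config$cv$seed),
               cfg = train_config(config$train$k, config$train$r,
                                  config$train$batch_size, config$train$lr,
                                  config$train$epochs, config$train$sce_alpha,
                                  config$train$sce_beta,
                                  config$train$log_clamp,
                                  config$train$weight_decay,
                                  config$train$seed),
               cutoff = config$evaluate$cutoff)
  evaluation <- evaluate_scoring(cv, cohort, cutoff = config$evaluate$cutoff,
                                 horizon_months = config$evaluate$horizon_months)

  manifest <- list(
    package_version = as.character(utils::packageVersion("odynr")),
    config = config,
    n_slides = nrow(cohort),
    n_scorable_slides = length(unique(features$slide_id)),
    dropped_slides = attr(features, "dropped_slides"),
    n_models = length(cv$models)
  )
  out <- list(cohort = cohort, repith = repith, threshold = threshold,
              features = features, cv = cv, evaluation = evaluation,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cv$mean_scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(cv$scores, file.path(out_dir, "scores_per_repeat.csv"))
    readr::write_csv(repith, file.path(out_dir, "repith.csv"))
    readr::write_csv(evaluation$metrics, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
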