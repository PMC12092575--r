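#' Train the patch MLP by iterative draw-and-rank sampling
#'
#' Weakly supervised training under slide-level labels: each epoch, every
#' slide contributes its `k` patches currently ranked highest for the
#' slide's own label (positive-class score for label-1 slides,
#' negative-class score for label-0 slides) plus `r` patches drawn uniformly
#' without replacement from the rest; the first epoch's ranking is uniform
#' random. Slides with fewer than `k + r` patches contribute all their
#' patches. The pooled selection is optimised in minibatches with Adam under
#' the symmetric cross-entropy loss. Fully deterministic given `cfg$seed`.
#'
#' When validation slides are supplied, the epoch with the best validation
#' slide-level AUROC is kept (checkpoint selection); otherwise the final
#' epoch's parameters are returned.
#'
#' @param features Feature tibble from [extract_features()] (training
#'   slides).
#' @param labels Named vector: slide-level binary outcome (1 =
#'   transformed), names are slide ids.
#' @param cfg A [train_config()].
#' @param spec An [mlp_spec()].
#' @param val_features,val_labels Optional held-out slides for checkpoint
#'   selection.
#' @return An `odyn_mlp` model: parameters, scaler, spec, config and
#'   per-epoch history.
#' @export
idars_train <- function(features, labels, cfg = train_config(),
                        spec = mlp_spec(), val_features = NULL,
                        val_labels = NULL) {
  fm <- features_matrix(features)
  keep <- fm$slide_id %in% names(labels)
  X <- fm$X[keep, , drop = FALSE]
  sid <- fm$slide_id[keep]
  slide_ids <- unique(sid)
  missing_slides <- setdiff(names(labels), slide_ids)
  drop_log(length(missing_slides), "slides with 0 patches excluded from training")
  labels <- labels[slide_ids]
  assert_that(length(unique(labels)) == 2,
              "at least one slide per class required",
              class = "odynr_validation_error")
  patch_rows <- split(seq_along(sid), sid)[slide_ids]

  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  params <- mlp_init(spec, derive_seed(cfg$seed, 1L))
  opt <- adam_init(params)
  history <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                            val_auroc = numeric(0), val_loss = numeric(0))
  best <- list(params = params, val_auroc = -Inf, val_loss = Inf)

  with_seed(derive_seed(cfg$seed, 2L), {
    for (epoch in seq_len(cfg$epochs)) {
      # --- draw-and-rank selection -------------------------------------
      sel <- unlist(lapply(seq_along(slide_ids), function(i) {
        rows <- patch_rows[[i]]
        n <- length(rows)
        if (n <= cfg$k + cfg$r) return(rows)
        top <- integer(0)
        if (cfg$k > 0) {
          score <- if (epoch == 1) {
            runif(n)
          } else {
            fw <- mlp_forward(params, Xs[rows, , drop = FALSE], spec)
            fw$P[, labels[i] + 1L]  # rank by the slide's own label class
          }
          top <- rows[order(score, decreasing = TRUE)[seq_len(cfg$k)]]
        }
        rest <- setdiff(rows, top)
        c(top, sample(rest, min(cfg$r, length(rest))))
      }), use.names = FALSE)
      y_sel <- rep(labels, vapply(patch_rows, length, integer(1)))[
        match(sel, unlist(patch_rows, use.names = FALSE))]
      y_sel <- unname(y_sel)

      # --- minibatch optimisation --------------------------------------
      ord <- sample(length(sel))
      sel <- sel[ord]; y_sel <- y_sel[ord]
      batches <- split(seq_along(sel),
                       ceiling(seq_along(sel) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- Xs[sel[b], , drop = FALSE]
        yb <- y_sel[b]
        mask <- if (spec$dropout > 0) {
          matrix(runif(length(b) * spec$hidden) >= spec$dropout,
                 length(b), spec$hidden)
        } else NULL
        fw <- mlp_forward(params, Xb, spec, dropout_mask = mask)
        ep_loss <- ep_loss + sum(sce_loss(fw$P, yb, cfg$sce_alpha,
                                          cfg$sce_beta, cfg$log_clamp))
        dZ <- sce_logit_grad(fw$P, yb, cfg$sce_alpha, cfg$sce_beta,
                             cfg$log_clamp)
        grads <- mlp_backward(params, fw, Xb, dZ, spec, dropout_mask = mask)
        upd <- adam_step(params, grads, opt, cfg$lr,
                         weight_decay = cfg$weight_decay %||% 0)
        params <- upd$params; opt <- upd$state
      }

      # --- validation checkpoint ---------------------------------------
      # primary criterion: slide-level validation AUROC; the coarse AUROC
      # on a handful of validation slides saturates quickly, so ties are
      # broken by the continuous slide-level cross-entropy
      va <- NA_real_; vl <- NA_real_
      if (!is.null(val_features) && length(unique(val_labels)) == 2) {
        m_tmp <- structure(list(params = params, scaler = scaler, spec = spec),
                           class = "odyn_mlp")
        vs <- score_slides(m_tmp, val_features)
        yv <- val_labels[vs$slide_id]
        va <- auroc(vs$odyn_score, yv)
        pv <- pmin(pmax(ifelse(yv == 1, vs$odyn_score, 1 - vs$odyn_score),
                        1e-12), 1)
        vl <- -mean(log(pv))
        if (va > best$val_auroc ||
            (va == best$val_auroc && vl < best$val_loss)) {
          best <- list(params = params, val_auroc = va, val_loss = vl)
        }
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = epoch, train_loss = ep_loss / length(sel), val_auroc = va,
        val_loss = vl))
    }
  })

  final <- if (is.finite(best$val_auroc)) best$params else params
  structure(list(params = final, scaler = scaler, spec = spec, cfg = cfg,
                 history = history, n_slides = length(slide_ids)),
            class = "odyn_mlp")
}

#' @export
print.odyn_mlp <- function(x, ...) {
  cat(sprintf("<odyn_mlp> %d-%d-%d, trained on %d slides, %d epochs\n",
              x$spec$input, x$spec$hidden, x$spec$output, x$n_slides,
              nrow(x$history)))
  invisible(x)
}

#' @export
glance.odyn_mlp <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    best_val_auroc = suppressWarnings(max(x$history$val_auroc, na.rm = TRUE)),
    n_slides = x$n_slides
  )
}

#' Aggregate patch scores into a slide score
#'
#' The slide-level score is the mean of the top 50% ranked patch scores;
#' with `n` patches that is the top `ceiling(n/2)` after sorting
#' descending (odd counts round up, so the set is never empty).
#'
#' @param patch_scores Numeric vector of per-patch positive-class
#'   probabilities.
#' @return The aggregated slide score.
#' @export
aggregate_slide <- function(patch_scores) {
  assert_that(length(patch_scores) >= 1, "no patch scores to aggregate",
              class = "odynr_validation_error")
  s <- sort(patch_scores, decreasing = TRUE)
  mean(s[seq_len(ceiling(length(s) / 2))])
}

#' Score slides with a trained model
#'
#' @param model An `odyn_mlp`.
#' @param features Feature tibble for the slides to score.
#' @param cutoff Risk-group dichotomisation cutoff on the slide score.
#' @return Tibble: `slide_id`, `odyn_score`, `n_patches`, `risk_group`.
#' @export
score_slides <- function(model, features, cutoff = 0.5) {
  fm <- features_matrix(features)
  scores <- predict_patches(model, fm$X)
  tibble::tibble(slide_id = fm$slide_id, score = scores) |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::summarise(odyn_score = aggregate_slide(.data$score),
                     n_patches = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(risk_group = ifelse(.data$odyn_score >= cutoff,
                                      "high", "low"))
}

#' Cross-validation plan
#'
#' Repeated patient-grouped stratified k-fold: all slides of one patient
#' share a fold, folds are stratified by outcome where feasible, and the
#' non-test patients are split 90/10 (by patient) into training and
#' validation sets for checkpoint selection.
#'
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats with different seeds (default 3).
#' @param val_frac Inner validation fraction (default 0.1).
#' @param seed Base seed; repeat seeds are derived from it.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(n_folds = 5L, n_repeats = 3L, val_frac = 0.1, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1, val_frac > 0, val_frac < 0.5)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "cv_plan")
}

# Patient-grouped stratified fold assignment: within each outcome class
# patients are shuffled and dealt round-robin.
assign_folds <- function(patients, outcomes, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(patients))
    for (cl in unique(outcomes)) {
      i <- which(outcomes == cl)
      i <- i[sample(length(i))]
      fold[i] <- rep_len(sample(n_folds), length(i))
    }
    stats::setNames(fold, patients)
  })
}

#' Repeated grouped cross-validation of the scoring pipeline
#'
#' Runs `n_folds x n_repeats` training jobs (15 under the default plan). In
#' each, one fold is held out for testing and the remaining patients are
#' split 90/10 into training/validation. Every slide receives one
#' out-of-fold score per repeat; scores are reported per repeat and as
#' their mean.
#'
#' @param cohort Cohort tibble ([read_cohort()]); slide labels are
#'   `transformed`.
#' @param features Feature tibble covering the cohort's scorable slides.
#' @param plan A [cv_plan()].
#' @param cfg A [train_config()].
#' @param spec An [mlp_spec()].
#' @param cutoff Risk-group cutoff passed to [score_slides()].
#' @return An `odyn_cv` object: `scores` (per repeat), `mean_scores`,
#'   `models` (list of length folds x repeats), `fold_table`.
#' @export
run_cv <- function(cohort, features, plan = cv_plan(), cfg = train_config(),
                   spec = mlp_spec(), cutoff = 0.5) {
  scorable <- unique(features$slide_id)
  co <- cohort[cohort$slide_id %in% scorable, ]
  drop_log(nrow(cohort) - nrow(co), "slides without scoring patches (excluded from CV)")
  pat <- co |>
    dplyr::distinct(.data$patient_id, .data$transformed)
  assert_that(nrow(pat) == length(unique(pat$patient_id)),
              "patients must have a unique outcome",
              class = "odynr_validation_error")
  assert_that(all(table(pat$transformed) >= 2),
              "need >= 2 patients per class for grouped CV",
              class = "odynr_validation_error")
  labels_all <- stats::setNames(co$transformed, co$slide_id)

  models <- list()
  scores <- list()
  fold_rows <- list()
  for (rep_i in seq_len(plan$n_repeats)) {
    folds <- assign_folds(pat$patient_id, pat$transformed, plan$n_folds,
                          derive_seed(plan$seed, rep_i))
    for (fold_i in seq_len(plan$n_folds)) {
      test_pat <- names(folds)[folds == fold_i]
      rest_pat <- names(folds)[folds != fold_i]
      rest_out <- pat$transformed[match(rest_pat, pat$patient_id)]
      val_pat <- with_seed(derive_seed(plan$seed, rep_i, fold_i), {
        unlist(lapply(unique(rest_out), function(cl) {
          p <- rest_pat[rest_out == cl]
          sample(p, max(1, round(plan$val_frac * length(p))))
        }))
      })
      train_pat <- setdiff(rest_pat, val_pat)
      sl <- function(p) co$slide_id[co$patient_id %in% p]
      f_train <- features[features$slide_id %in% sl(train_pat), ]
      f_val <- features[features$slide_id %in% sl(val_pat), ]
      f_test <- features[features$slide_id %in% sl(test_pat), ]
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, rep_i, fold_i, 7L)
      model <- idars_train(f_train, labels_all[unique(f_train$slide_id)],
                           cfg_i, spec,
                           val_features = f_val,
                           val_labels = labels_all[unique(f_val$slide_id)])
      models[[length(models) + 1L]] <- model
      if (nrow(f_test) > 0) {
        s <- score_slides(model, f_test, cutoff = cutoff)
        s$repeat_i <- rep_i; s$fold <- fold_i
        scores[[length(scores) + 1L]] <- s
      }
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        repeat_i = rep_i, fold = fold_i,
        test_patients = list(test_pat), train_patients = list(train_pat),
        val_patients = list(val_pat))
    }
  }
  scores <- dplyr::bind_rows(scores)
  mean_scores <- scores |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::summarise(odyn_score = mean(.data$odyn_score),
                     n_repeats = dplyr::n_distinct(.data$repeat_i),
                     .groups = "drop") |>
    dplyr::mutate(risk_group = ifelse(.data$odyn_score >= cutoff,
                                      "high", "low"))
  structure(list(scores = scores, mean_scores = mean_scores,
                 models = models, fold_table = dplyr::bind_rows(fold_rows),
                 plan = plan, cutoff = cutoff),
            class = "odyn_cv")
}

#' @export
print.odyn_cv <- function(x, ...) {
  cat(sprintf("<odyn_cv> %d models (%d folds x %d repeats), %d slides scored\n",
              length(x$models), x$plan$n_folds, x$plan$n_repeats,
              nrow(x$mean_scores)))
  invisible(x)
}

#' @export
tidy.odyn_cv <- function(x, ...) x$scores

#' @export
glance.odyn_cv <- function(x, ...) {
  tibble::tibble(n_models = length(x$models),
                 n_folds = x$plan$n_folds, n_repeats = x$plan$n_repeats,
                 n_slides = nrow(x$mean_scores))
}

#' Ensemble the cross-validation models on external data
#'
#' Each of the cross-validation models scores the external slides
#' independently (patch prediction then top-50% aggregation); the ensemble
#' slide score is the mean of the per-model slide scores.
#'
#' @param models List of `odyn_mlp` models (all folds x repeats).
#' @param features Feature tibble of the external slides.
#' @param cutoff Risk-group cutoff.
#' @return Tibble: `slide_id`, `odyn_score`, `risk_group`, plus the
#'   per-model score matrix as attribute `per_model`.
#' @export
ensemble_external <- function(models, features, cutoff = 0.5) {
  assert_that(length(models) >= 1 &&
                all(vapply(models, inherits, logical(1), "odyn_mlp")),
              "`models` must be a non-empty list of odyn_mlp fits",
              class = "odynr_validation_error")
  per_model <- lapply(models, function(m) score_slides(m, features))
  ids <- per_model[[1]]$slide_id
  mat <- vapply(per_model, function(s) s$odyn_score[match(ids, s$slide_id)],
                numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  out <- tibble::tibble(
    slide_id = ids,
    odyn_score = rowMeans(mat)
  ) |>
    dplyr::mutate(risk_group = ifelse(.data$odyn_score >= cutoff,
                                      "high", "low"))
  attr(out, "per_model") <- mat
  out
}
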