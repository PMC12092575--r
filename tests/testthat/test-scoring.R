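test_that("repeated grouped CV emits folds x repeats models with grouped folds", {
  toy <- toy_features(n_slides = 20, n_patches = 4, delta = 2.5, seed = 41)
  cohort <- toy_cohort(toy$labels)
  plan <- cv_plan(n_folds = 5, n_repeats = 3, seed = 11)
  cfg <- train_config(k = 1, r = 3, epochs = 6, batch_size = 32, seed = 2)
  cv <- suppressMessages(run_cv(cohort, toy$features, plan, cfg))

  expect_equal(length(cv$models), 15)
  expect_equal(nrow(cv$fold_table), 15)
  # 20 patients, 5 folds -> 4 test patients per fold
  expect_true(all(vapply(cv$fold_table$test_patients, length, integer(1)) == 4))
  # every slide scored once per repeat
  per_rep <- table(cv$scores$repeat_i)
  expect_true(all(per_rep == 20))
  expect_equal(sort(unique(cv$scores$slide_id)), sort(cohort$slide_id))

  # no patient's slides straddle train/val/test in any job
  for (i in seq_len(nrow(cv$fold_table))) {
    row <- cv$fold_table[i, ]
    expect_length(intersect(row$test_patients[[1]], row$train_patients[[1]]), 0)
    expect_length(intersect(row$test_patients[[1]], row$val_patients[[1]]), 0)
    expect_length(intersect(row$train_patients[[1]], row$val_patients[[1]]), 0)
  }

  # repeats use different fold assignments
  f1 <- cv$scores$fold[cv$scores$repeat_i == 1]
  f2 <- cv$scores$fold[cv$scores$repeat_i == 2]
  expect_false(identical(f1[order(cv$scores$slide_id[cv$scores$repeat_i == 1])],
                         f2[order(cv$scores$slide_id[cv$scores$repeat_i == 2])]))
})

test_that("patients with multiple slides never straddle a fold boundary", {
  toy <- toy_features(n_slides = 16, n_patches = 3, delta = 2, seed = 43)
  cohort <- toy_cohort(toy$labels)
  # pair up slides under 8 patients
  cohort$patient_id <- rep(sprintf("pt%02d", 1:8), each = 2)
  # patients must share outcome: regenerate labels patient-wise
  pat_lab <- stats::setNames(rep(c(0L, 1L), 4), sprintf("pt%02d", 1:8))
  cohort$transformed <- pat_lab[cohort$patient_id]
  labels <- stats::setNames(cohort$transformed, cohort$slide_id)
  plan <- cv_plan(n_folds = 4, n_repeats = 2, seed = 5)
  cfg <- train_config(k = 1, r = 2, epochs = 4, batch_size = 16, seed = 2)
  cv <- suppressMessages(run_cv(cohort, toy$features, plan, cfg))
  slide_pat <- stats::setNames(cohort$patient_id, cohort$slide_id)
  straddle <- cv$scores |>
    dplyr::mutate(patient = slide_pat[slide_id]) |>
    dplyr::group_by(repeat_i, patient) |>
    dplyr::summarise(nfold = dplyr::n_distinct(fold), .groups = "drop")
  expect_true(all(straddle$nfold == 1))
})

test_that("CV reruns are bit-identical and single-patient cohorts error", {
  toy <- toy_features(n_slides = 12, n_patches = 3, delta = 2, seed = 47)
  cohort <- toy_cohort(toy$labels)
  plan <- cv_plan(n_folds = 3, n_repeats = 2, seed = 21)
  cfg <- train_config(k = 1, r = 2, epochs = 4, batch_size = 16, seed = 8)
  cv1 <- suppressMessages(run_cv(cohort, toy$features, plan, cfg))
  cv2 <- suppressMessages(run_cv(cohort, toy$features, plan, cfg))
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$mean_scores, cv2$mean_scores)

  tiny <- cohort[1:2, ]
  tiny$patient_id <- "only_one"
  tiny$transformed <- c(0L, 1L)
  expect_error(suppressMessages(
    run_cv(tiny, toy$features[toy$features$slide_id %in% tiny$slide_id, ],
           plan, cfg)),
    class = "odynr_validation_error")
})

test_that("external ensembling equals the brute-force mean of per-model scores", {
  toy <- toy_features(n_slides = 10, n_patches = 4, delta = 2, seed = 53)
  ext <- toy_features(n_slides = 6, n_patches = 4, delta = 2, seed = 54,
                      prefix = "e")
  cfg <- train_config(k = 1, r = 3, epochs = 4, batch_size = 16, seed = 1)
  models <- lapply(1:5, function(i) {
    cfg$seed <- i
    suppressMessages(idars_train(toy$features, toy$labels, cfg))
  })
  ens <- ensemble_external(models, ext$features)
  per_model <- attr(ens, "per_model")
  brute <- vapply(models, function(m) {
    score_slides(m, ext$features)$odyn_score[
      match(ens$slide_id, score_slides(m, ext$features)$slide_id)]
  }, numeric(nrow(ens)))
  expect_equal(ens$odyn_score, rowMeans(brute), tolerance = 1e-12)
  expect_equal(per_model, brute, ignore_attr = TRUE)

  # identical models: ensemble equals the single-model score
  same <- ensemble_external(models[c(1, 1, 1)], ext$features)
  single <- score_slides(models[[1]], ext$features)
  expect_equal(same$odyn_score,
               single$odyn_score[match(same$slide_id, single$slide_id)])
})
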