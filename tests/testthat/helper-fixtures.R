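# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small synthetic cohort with a strong transformation effect.
small_effect_cohort <- function() {
  fixture("small_effect", function() {
    suppressMessages(generate_cohort(synth_config(
      n_patients = 10, n_controls = 2, nuclear_effect = 1.5, seed = 42)))
  })
}

# Hand-made feature tibble: `n_slides` slides x `n_patches` patches of 168
# features where the first feature carries the label signal (shift `delta`).
toy_features <- function(n_slides, n_patches, delta, seed, prefix = "s") {
  withr::with_seed(seed, {
    rows <- list()
    labels <- rep(c(0L, 1L), length.out = n_slides)
    for (i in seq_len(n_slides)) {
      X <- matrix(rnorm(n_patches * 168), n_patches, 168)
      X[, 1] <- X[, 1] + delta * labels[i]
      colnames(X) <- feature_names()
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(slide_id = sprintf("%s%02d", prefix, i),
                       patch_id = sprintf("p%d", seq_len(n_patches)),
                       x = 0L, y = 0L, n_nuclei = 10L),
        tibble::as_tibble(X))
    }
    list(features = dplyr::bind_rows(rows),
         labels = stats::setNames(labels, sprintf("%s%02d", prefix,
                                                  seq_len(n_slides))))
  })
}

# Minimal cohort for the toy features (one slide per patient).
toy_cohort <- function(labels) {
  tibble::tibble(
    slide_id = names(labels), patient_id = paste0("pt_", names(labels)),
    transformed = unname(labels),
    follow_up_months = unname(ifelse(labels == 1, 24, 96)),
    who_grade = "moderate", binary_grade = "low_risk",
    age = 60, sex = "female", site = "tongue", cohort_tag = "internal"
  )
}

# A random binary mask_raster.
random_mask <- function(nr, nc, p = 0.3, mpp = 0.5, seed = 1) {
  withr::with_seed(seed, {
    mask_raster(matrix(rbinom(nr * nc, 1, p), nr, nc), mpp = mpp)
  })
}

expect_no_message_class <- function(expr) invisible(suppressMessages(expr))

# all permutations of 1..n (tiny n only; exhaustive permutation oracles)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(n - 1)
    for (r in rest) {
      v <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, v[r])
    }
  }
  out
}

# The 60-slide planted-effect pipeline run shared by the acceptance blocks.
acceptance_effect_run <- function() {
  fixture("acceptance_eff", function() {
    suppressMessages(run_pipeline(odyn_config(overrides = list(
      synth = list(n_patients = 60, n_controls = 0, nuclear_effect = 1,
                   seed = 7)))))
  })
}
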