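test_that("same seed regenerates bit-identical slides", {
  cfg <- synth_config(n_patients = 2, seed = 13)
  a <- suppressMessages(generate_slide(cfg, 1, "s", slide_seed = 77))
  b <- suppressMessages(generate_slide(cfg, 1, "s", slide_seed = 77))
  expect_identical(a$epithelium$pixels, b$epithelium$pixels)
  expect_identical(a$dysplasia$pixels, b$dysplasia$pixels)
  expect_identical(a$nuclei, b$nuclei)
})

test_that("dysplasia is a subset of the epithelium on every slide", {
  b <- small_effect_cohort()
  for (sl in b$slides) {
    expect_true(all(sl$dysplasia$pixels <= sl$epithelium$pixels))
  }
})

test_that("full-range dysplasia equals the epithelium", {
  cfg <- synth_config(n_patients = 2,
                      dysplasia_fraction_range = list(
                        non_transforming = c(1, 1), transforming = c(1, 1)),
                      seed = 5)
  sl <- suppressMessages(generate_slide(cfg, 1, "s", slide_seed = 5))
  expect_identical(sl$dysplasia$pixels, sl$epithelium$pixels)
})

test_that("nuclei are placed in their compartments with separated centroids", {
  sl <- small_effect_cohort()$slides[[1]]
  nuc <- assign_compartment(sl$nuclei, sl$epithelium)
  on_dys <- mask_value_at <- odynr:::mask_value_at
  dys_val <- on_dys(sl$dysplasia, nuc$centroid_x, nuc$centroid_y)
  ep_val <- on_dys(sl$epithelium, nuc$centroid_x, nuc$centroid_y)
  expect_true(all(dys_val[nuc$raw_class == "dysplastic_epithelial"] == 1))
  expect_true(all(ep_val[nuc$raw_class == "normal_epithelial"] == 1 &
                    dys_val[nuc$raw_class == "normal_epithelial"] == 0))
  expect_true(all(c("iel", "pel") %in% nuc$compartment_class))
  d <- stats::dist(cbind(nuc$centroid_x, nuc$centroid_y))
  expect_gt(min(d), 6 / sl$epithelium$mpp * 0.99)
})

test_that("transformation counts follow the deterministic sorted draw", {
  cfg <- synth_config(n_patients = 20, transform_fraction = 0.5, seed = 3,
                      canvas_size = 768)
  b <- suppressMessages(generate_cohort(cfg))
  pat <- dplyr::distinct(b$cohort, patient_id, transformed)
  expect_equal(sum(pat$transformed), 10)
})

test_that("censoring policy: censor_rate 0 censors only at the horizon", {
  cfg <- synth_config(n_patients = 12, censor_rate = 0, seed = 4)
  b <- suppressMessages(generate_cohort(cfg))
  non_tr <- b$cohort[b$cohort$transformed == 0 & !b$cohort$is_control, ]
  expect_true(all(non_tr$follow_up_months == cfg$horizon_months))
})

test_that("generated cohorts pass the cohort validators and bundle round-trips", {
  b <- small_effect_cohort()
  expect_silent(co <- suppressMessages(validate_cohort(
    b$cohort[, odynr:::COHORT_COLUMNS])))
  dir <- withr::local_tempdir()
  write_cohort_bundle(b, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), nrow(b$cohort))
  sid <- b$cohort$slide_id[1]
  ep <- read_mask(file.path(dir, sprintf("%s_epithelium.png", sid)),
                  mpp = b$config$mask_mpp)
  expect_identical(ep$pixels, b$slides[[sid]]$epithelium$pixels)
  nuc <- suppressMessages(read_nuclei(
    file.path(dir, sprintf("%s_nuclei.geojson", sid))))
  expect_equal(nrow(nuc), nrow(b$slides[[sid]]$nuclei))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("higher nuclear effect shifts PEL density and dysplastic size upward", {
  cfg0 <- synth_config(n_patients = 2, nuclear_effect = 0, seed = 10)
  cfg2 <- synth_config(n_patients = 2, nuclear_effect = 2, seed = 10)
  pel_count <- function(cfg, outcome) {
    sl <- suppressMessages(generate_slide(cfg, outcome, "s", slide_seed = 88))
    nuc <- assign_compartment(sl$nuclei, sl$epithelium)
    sum(nuc$compartment_class == "pel")
  }
  # same seed, same geometry; outcome=1 at effect 2 vs effect 0
  expect_gt(pel_count(cfg2, 1), 1.5 * pel_count(cfg0, 1))

  area_de <- function(cfg) {
    sl <- suppressMessages(generate_slide(cfg, 1, "s", slide_seed = 88))
    m <- suppressMessages(nuclei_morphometrics(
      sl$nuclei[sl$nuclei$raw_class == "dysplastic_epithelial", ],
      mpp = cfg$mask_mpp))
    mean(m$area_um2)
  }
  expect_gt(area_de(cfg2), 1.3 * area_de(cfg0))
})

test_that("at zero nuclear effect the outcomes' features are exchangeable", {
  cfg <- synth_config(n_patients = 16, nuclear_effect = 0,
                      transform_fraction = 0.5, seed = 19)
  b <- suppressMessages(generate_cohort(cfg))
  pel_per_slide <- vapply(b$slides, function(sl) {
    nuc <- assign_compartment(sl$nuclei, sl$epithelium)
    sum(nuc$compartment_class == "pel")
  }, numeric(1))
  y <- b$cohort$transformed[match(names(pel_per_slide), b$cohort$slide_id)]
  mw <- mann_whitney_rrb(pel_per_slide[y == 1], pel_per_slide[y == 0])
  expect_gt(mw$p_value, 0.01)
})
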