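test_that("the registry defines exactly 168 uniquely named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 168)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(sum(reg$block == "morphological"), 72)
  expect_equal(sum(reg$block == "spatial"), 96)
  expect_identical(feature_names(), reg$name)
})

test_that("compartment assignment splits 'other' by the epithelium pixel", {
  ep <- mask_raster(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                          c(0, 0, 0, 0), c(0, 0, 0, 0)), 1, "s")
  sq <- function(cx, cy) cbind(cx + c(-.3, .3, .3, -.3), cy + c(-.3, -.3, .3, .3))
  nuc <- nuclei_tibble(
    c("a", "b", "c", "d"),
    c("other", "other", "dysplastic_epithelial", "normal_epithelial"),
    list(sq(0, 0), sq(3, 3), sq(3, 0), sq(0, 3)))
  out <- assign_compartment(nuc, ep)
  expect_equal(out$compartment_class[out$nucleus_id == "a"], "iel")
  expect_equal(out$compartment_class[out$nucleus_id == "b"], "pel")
  # epithelial classes pass through regardless of position
  expect_equal(out$compartment_class[out$nucleus_id == "c"],
               "dysplastic_epithelial")
  expect_equal(out$compartment_class[out$nucleus_id == "d"],
               "normal_epithelial")
})

make_test_slide <- function(n_per_class = 8, size = 64, seed = 9) {
  withr::with_seed(seed, {
    ep <- matrix(0L, size, size); ep[, 1:(size / 2)] <- 1L
    dy <- matrix(0L, size, size); dy[, 1:(size / 4)] <- 1L
    regions <- list(dysplastic_epithelial = c(1, size / 4),
                    normal_epithelial = c(size / 4 + 2, size / 2),
                    other_in = c(1, size / 2),
                    other_out = c(size / 2 + 2, size))
    ids <- character(0); cls <- character(0); contours <- list()
    for (k in names(regions)) {
      for (i in seq_len(n_per_class)) {
        cx <- runif(1, regions[[k]][1], regions[[k]][2] - 1)
        cy <- runif(1, 2, size - 2)
        contours <- c(contours, list(odynr:::ellipse_polygon(
          cx, cy, runif(1, 20, 40), 0.5, runif(1, 0, pi), 1)))
        ids <- c(ids, paste0(k, i))
        cls <- c(cls, if (grepl("other", k)) "other" else k)
      }
    }
    list(epithelium = mask_raster(ep, 1, "t"), dysplasia = mask_raster(dy, 1, "t"),
         nuclei = nuclei_tibble(ids, cls, contours))
  })
}

test_that("feature vectors are length-168, finite, deterministic, translation-invariant", {
  sl <- make_test_slide()
  g <- suppressWarnings(make_patch_grid(c(64, 64), 1, 64, 0, 1))
  f1 <- suppressMessages(extract_features(sl$epithelium, sl$dysplasia,
                                          sl$nuclei, g))
  expect_equal(ncol(f1) - 5, 168)
  X <- as.matrix(f1[, feature_names()])
  expect_true(all(is.finite(X)))

  f2 <- suppressMessages(extract_features(sl$epithelium, sl$dysplasia,
                                          sl$nuclei, g))
  expect_identical(f1, f2)

  # translate nuclei and masks by the same offset: vector unchanged
  off <- 32
  big <- matrix(0L, 96, 96)
  big[(off + 1):(off + 64), (off + 1):(off + 64)] <- sl$epithelium$pixels
  big_dy <- matrix(0L, 96, 96)
  big_dy[(off + 1):(off + 64), (off + 1):(off + 64)] <- sl$dysplasia$pixels
  nuc2 <- sl$nuclei
  nuc2$contour <- lapply(nuc2$contour, function(p) p + off)
  nuc2$centroid_x <- nuc2$centroid_x + off
  nuc2$centroid_y <- nuc2$centroid_y + off
  g2 <- make_patch_grid(c(96, 96), 1, 64, 0, 1)
  f3 <- suppressMessages(extract_features(mask_raster(big, 1, "t"),
                                          mask_raster(big_dy, 1, "t"),
                                          nuc2, g2))
  shifted <- f3[f3$x == off & f3$y == off, feature_names()]
  expect_equal(as.numeric(shifted), as.numeric(f1[1, feature_names()]),
               tolerance = 1e-10)
})

test_that("empty patches give the all-zero vector; single nuclei impute 0", {
  ep <- mask_raster(matrix(0L, 32, 32), 1, "e")
  g <- suppressWarnings(make_patch_grid(c(32, 32), 1, 32, 0, 1))
  f <- suppressMessages(extract_features(ep, ep, nuclei_tibble(
    character(0), character(0), list()), g))
  expect_equal(f$n_nuclei, 0)
  expect_true(all(as.matrix(f[, feature_names()]) == 0))

  # one IEL nucleus: its count is 1, other class counts 0, nn stats imputed 0
  ep2 <- mask_raster(matrix(1L, 32, 32), 1, "e2")
  dy2 <- mask_raster(matrix(0L, 32, 32), 1, "e2")
  nuc <- nuclei_tibble("n1", "other",
                       list(cbind(16 + c(-2, 2, 2, -2), 16 + c(-2, -2, 2, 2))))
  f2 <- suppressMessages(extract_features(ep2, dy2, nuc, g))
  expect_equal(f2$iel_count, 1)
  expect_equal(f2$pel_count + f2$dysplastic_epithelial_count +
                 f2$normal_epithelial_count, 0)
  expect_equal(f2$iel_nn1_mean, 0)
  expect_equal(f2$all_nn1_mean, 0)
  expect_gt(f2$iel_area_um2_mean, 0)
})

test_that("counts over a non-overlapping grid sum to the slide total", {
  sl <- make_test_slide(n_per_class = 10)
  g <- make_patch_grid(c(64, 64), 1, 32, 0, 1)  # 4 disjoint patches
  f <- suppressMessages(extract_features(sl$epithelium, sl$dysplasia,
                                         sl$nuclei, g))
  count_cols <- sprintf("%s_count", c("dysplastic_epithelial",
                                      "normal_epithelial", "iel", "pel"))
  expect_equal(sum(as.matrix(f[, count_cols])), nrow(sl$nuclei))
  expect_equal(sum(f$n_nuclei), nrow(sl$nuclei))
})

test_that("patch tissue fractions partition the patch", {
  sl <- make_test_slide()
  g <- suppressWarnings(make_patch_grid(c(64, 64), 1, 64, 0, 1))
  f <- suppressMessages(extract_features(sl$epithelium, sl$dysplasia,
                                         sl$nuclei, g))
  expect_equal(f$tissue_frac_dysplastic_epith + f$tissue_frac_normal_epith +
                 f$tissue_frac_other, 1, tolerance = 1e-9)
  expect_equal(f$tissue_frac_dysplastic_epith, 0.25)
  expect_equal(f$tissue_frac_normal_epith, 0.25)
})

test_that("known-morphology nuclei recover the generating mean area", {
  withr::with_seed(5, {
    areas <- runif(10, 30, 60)
    contours <- lapply(seq_along(areas), function(i) {
      odynr:::ellipse_polygon(runif(1, 10, 50), runif(1, 10, 50),
                              areas[i], 0.6, runif(1, 0, pi), 1)
    })
    nuc <- nuclei_tibble(sprintf("n%d", 1:10), rep("other", 10), contours)
    ep <- mask_raster(matrix(1L, 64, 64), 1, "m")
    dy <- mask_raster(matrix(0L, 64, 64), 1, "m")
    g <- suppressWarnings(make_patch_grid(c(64, 64), 1, 64, 0, 1))
    f <- suppressMessages(extract_features(ep, dy, nuc, g))
    expect_equal(f$iel_area_um2_mean, mean(areas), tolerance = 0.02)
  })
})
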