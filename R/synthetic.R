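#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the three inputs of the downstream pipeline —
#' epithelium/dysplasia masks, classified nuclear polygons and a clinical
#' cohort table — with a controllable transformation effect. The epithelium
#' is a thick smoothed band (mimicking mucosal architecture and guaranteeing
#' the dysplasia-subset invariant), dysplasia a contiguous sub-band whose
#' area fraction is drawn from the outcome's range, and nuclei are ellipses
#' polygonised at 16 vertices with class-specific morphology so expected
#' morphometrics have closed forms. `nuclear_effect` is a standardised shift:
#' in transforming slides the dysplastic-nucleus area mean moves up by
#' `effect` class SDs (with extra pleomorphism) and the stromal
#' "other"-nucleus (PEL) density is multiplied by `1 + effect`. Event times
#' for transforming patients are exponential with rate
#' `log(2)/30 * exp(nuclear_effect)` months^-1, a proportional-hazards
#' generator; non-transforming patients are censored at the administrative
#' horizon or, with probability `censor_rate`, earlier.
#'
#' @param n_patients Number of patients.
#' @param slides_per_patient Slides per patient (outcome shared).
#' @param n_controls Patients whose slides are non-dysplastic controls
#'   (near-zero dysplasia, no grades); counted inside `n_patients`.
#' @param canvas_size Square mask side in pixels at `mask_mpp`.
#' @param mask_mpp Mask resolution (microns per pixel).
#' @param transform_fraction Fraction of OED patients that transform
#'   (assigned deterministically by sorted draw).
#' @param dysplasia_fraction_range Named list of `(low, high)` dysplasia
#'   area-fraction ranges for `non_transforming` and `transforming` slides.
#' @param control_dysplasia_range Range for control slides (false-positive
#'   speckle).
#' @param nuclear_effect Standardised transformation effect (>= 0).
#' @param censor_rate Probability of early censoring for non-transforming
#'   patients.
#' @param horizon_months Administrative follow-up horizon.
#' @param densities Expected nuclei per mm^2 by compartment.
#' @param morphology Per-class nuclear morphology (area mean/CV in um^2,
#'   mean eccentricity).
#' @param seed Integer seed; per-slide substreams are derived from it, so
#'   slide regeneration is order-independent.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 20L,
                         slides_per_patient = 1L,
                         n_controls = 0L,
                         canvas_size = 768L,
                         mask_mpp = 0.5,
                         transform_fraction = 0.4,
                         dysplasia_fraction_range = list(
                           non_transforming = c(0.3, 0.6),
                           transforming = c(0.3, 0.6)),
                         control_dysplasia_range = c(0, 0.03),
                         nuclear_effect = 1,
                         censor_rate = 0.1,
                         horizon_months = 120,
                         densities = c(dysplastic_epithelial = 6000,
                                       normal_epithelial = 5000,
                                       iel = 1200,
                                       pel = 700),
                         morphology = list(
                           dysplastic_epithelial = list(area_mean = 55,
                                                        area_cv = 0.35,
                                                        ecc = 0.75),
                           normal_epithelial = list(area_mean = 35,
                                                    area_cv = 0.20,
                                                    ecc = 0.60),
                           other = list(area_mean = 18, area_cv = 0.15,
                                        ecc = 0.40)),
                         seed = 1L) {
  ranges <- c(dysplasia_fraction_range, list(control = control_dysplasia_range))
  for (r in ranges) {
    stopifnot(length(r) == 2, all(r >= 0 & r <= 1), r[1] <= r[2])
  }
  stopifnot(transform_fraction >= 0, transform_fraction <= 1,
            censor_rate >= 0, censor_rate <= 1, nuclear_effect >= 0,
            n_controls >= 0, n_controls < n_patients)
  assert_that(canvas_size * mask_mpp / 0.5 >= 512,
              "canvas must cover >= 512 px at the 0.5 mpp scoring resolution",
              class = "odynr_generation_error")
  structure(list(
    n_patients = as.integer(n_patients),
    slides_per_patient = as.integer(slides_per_patient),
    n_controls = as.integer(n_controls),
    canvas_size = as.integer(canvas_size), mask_mpp = mask_mpp,
    transform_fraction = transform_fraction,
    dysplasia_fraction_range = dysplasia_fraction_range,
    control_dysplasia_range = control_dysplasia_range,
    nuclear_effect = nuclear_effect, censor_rate = censor_rate,
    horizon_months = horizon_months, densities = densities,
    morphology = morphology, seed = as.integer(seed)
  ), class = "synth_config")
}

# Smooth epithelial band mask: centre line is a sum of two sinusoids across
# the columns, thickness is a drawn half-width.
random_band_mask <- function(size) {
  xs <- seq_len(size)
  a1 <- runif(1, 0.05, 0.12) * size
  a2 <- runif(1, 0.02, 0.06) * size
  f1 <- runif(1, 0.5, 1.2); f2 <- runif(1, 1.5, 2.5)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  y0 <- size / 2 + a1 * sin(2 * pi * f1 * xs / size + p1) +
    a2 * sin(2 * pi * f2 * xs / size + p2)
  hw <- runif(1, 0.16, 0.24) * size
  rows <- matrix(seq_len(size), size, size)
  centre <- matrix(y0, size, size, byrow = TRUE)
  (abs(rows - centre) <= hw) * 1L
}

# Contiguous column sub-band of the epithelium achieving approximately the
# requested dysplasia area fraction.
dysplasia_subband <- function(epithelium, fraction) {
  if (fraction >= 1) return(epithelium)
  out <- epithelium * 0L
  if (fraction <= 0) return(out)
  colsum <- colSums(epithelium)
  total <- sum(colsum)
  if (total == 0) return(out)
  target <- fraction * total
  start <- sample(which(colsum > 0), 1)
  csum <- cumsum(colsum[start:length(colsum)])
  end <- start + which(csum >= target)[1] - 1
  if (is.na(end)) {
    # extend left when the right tail is insufficient
    deficit <- target - csum[length(csum)]
    lsum <- cumsum(rev(colsum[seq_len(start - 1)]))
    k <- which(lsum >= deficit)[1]
    lo <- if (is.na(k)) 1L else start - k
    cols <- lo:length(colsum)
  } else {
    cols <- start:end
  }
  out[, cols] <- epithelium[, cols]
  out
}

# Draw one ellipse nucleus polygon (16 vertices, pixel coordinates). Semi-
# axes are scaled so the polygon area equals the drawn target area exactly.
ellipse_polygon <- function(cx, cy, area_um2, ecc, theta, mpp,
                            n_vertices = 16L) {
  c_n <- (n_vertices / 2) * sin(2 * pi / n_vertices)
  ratio <- 1 / sqrt(1 - ecc^2)                      # a / b
  b <- sqrt(area_um2 / (c_n * ratio))
  a <- b * ratio
  psi <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  ex <- a * cos(psi); ey <- b * sin(psi)
  cbind(cx + (ex * cos(theta) - ey * sin(theta)) / mpp,
        cy + (ex * sin(theta) + ey * cos(theta)) / mpp)
}

# Place `n` centroids uniformly on the positive pixels of `region`, keeping
# a minimum separation (px) from all previously accepted centroids.
place_centroids <- function(region, n, min_sep, accepted) {
  pos <- which(region == 1L)
  if (length(pos) == 0 || n == 0) return(matrix(numeric(0), 0, 2))
  cand_n <- min(length(pos), 6L * n)
  pix <- sample(pos, cand_n, replace = FALSE)
  # pixel index -> 0-based x (col), y (row) with subpixel jitter
  cy <- (pix - 1) %% nrow(region) + runif(cand_n, -0.5, 0.5)
  cx <- (pix - 1) %/% nrow(region) + runif(cand_n, -0.5, 0.5)
  keep <- matrix(numeric(0), 0, 2)
  all_pts <- accepted
  for (i in seq_len(cand_n)) {
    if (nrow(keep) >= n) break
    if (nrow(all_pts) > 0) {
      d2 <- (all_pts[, 1] - cx[i])^2 + (all_pts[, 2] - cy[i])^2
      if (min(d2) < min_sep^2) next
    }
    keep <- rbind(keep, c(cx[i], cy[i]))
    all_pts <- rbind(all_pts, c(cx[i], cy[i]))
  }
  keep
}

#' Generate one synthetic slide
#'
#' Produces co-registered epithelium and dysplasia masks plus a classified
#' nuclei table. Dysplastic-class nuclei are placed inside dysplasia,
#' normal-class inside non-dysplastic epithelium, and "other" nuclei both
#' inside the epithelium and in the stroma; for `outcome = 1` the stromal
#' "other" density and the dysplastic-nucleus size/pleomorphism are
#' increased by the configured `nuclear_effect`. Centroids are
#' non-overlapping (minimum separation).
#'
#' @param config A [synth_config()].
#' @param outcome Binary transformation outcome of the slide (`"control"`
#'   allowed for non-dysplastic control slides).
#' @param slide_id Identifier.
#' @param slide_seed Substream seed (derive from the config seed).
#' @return List: `epithelium`, `dysplasia` ([mask_raster()]), `nuclei`
#'   tibble, `dysplasia_fraction` drawn.
#' @export
generate_slide <- function(config, outcome, slide_id = "s1",
                           slide_seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(slide_seed, {
    size <- config$canvas_size
    mpp <- config$mask_mpp
    ep <- random_band_mask(size)
    assert_that(sum(ep) > 0.02 * size^2,
                "canvas too small to fit the epithelial band",
                class = "odynr_generation_error")
    rng <- if (identical(outcome, "control")) {
      config$control_dysplasia_range
    } else if (outcome == 1) {
      config$dysplasia_fraction_range$transforming
    } else {
      config$dysplasia_fraction_range$non_transforming
    }
    frac <- runif(1, rng[1], rng[2])
    dy <- dysplasia_subband(ep, frac)

    px_per_mm2 <- (1000 / mpp)^2   # pixels per mm^2
    effect <- if (identical(outcome, 1) || identical(outcome, 1L)) {
      config$nuclear_effect
    } else 0
    dens <- config$densities
    dens[["pel"]] <- dens[["pel"]] * (1 + effect)

    morph <- config$morphology
    de <- morph$dysplastic_epithelial
    de_mean <- de$area_mean * (1 + effect * de$area_cv)
    de_cv <- de$area_cv * (1 + 0.3 * effect)
    de_ecc <- min(0.92, de$ecc + 0.06 * effect)

    stroma <- (ep == 0L) * 1L
    normal_ep <- ((ep == 1L) & (dy == 0L)) * 1L
    regions <- list(
      dysplastic_epithelial = dy,
      normal_epithelial = normal_ep,
      iel = ep,
      pel = stroma
    )
    min_sep <- 6 / mpp  # 6 um centre separation
    accepted <- matrix(numeric(0), 0, 2)
    ids <- character(0); cls <- character(0); contours <- list()
    for (k in names(regions)) {
      area_mm2 <- sum(regions[[k]]) / px_per_mm2
      n_k <- rpois(1, dens[[k]] * area_mm2)
      pts <- place_centroids(regions[[k]], n_k, min_sep, accepted)
      accepted <- rbind(accepted, pts)
      if (nrow(pts) == 0) next
      par <- switch(k,
        dysplastic_epithelial = list(m = de_mean, cv = de_cv, ecc = de_ecc),
        normal_epithelial = list(m = morph$normal_epithelial$area_mean,
                                 cv = morph$normal_epithelial$area_cv,
                                 ecc = morph$normal_epithelial$ecc),
        list(m = morph$other$area_mean, cv = morph$other$area_cv,
             ecc = morph$other$ecc))
      raw <- if (k %in% c("iel", "pel")) "other" else k
      for (i in seq_len(nrow(pts))) {
        a <- max(5, rnorm(1, par$m, par$cv * par$m))
        e <- min(0.95, max(0.05, rnorm(1, par$ecc, 0.08)))
        contours <- c(contours, list(ellipse_polygon(
          pts[i, 1], pts[i, 2], a, e, runif(1, 0, pi), mpp)))
        ids <- c(ids, sprintf("%s_%s_%03d", slide_id, k, i))
        cls <- c(cls, raw)
      }
    }
    nuclei <- nuclei_tibble(ids, cls, contours)
    list(
      epithelium = mask_raster(ep, mpp, slide_id),
      dysplasia = mask_raster(dy, mpp, slide_id),
      nuclei = nuclei,
      dysplasia_fraction = frac
    )
  })
}

#' Generate a complete synthetic cohort
#'
#' Assigns transformation outcomes to exactly
#' `round(transform_fraction * n_oed)` OED patients (deterministic sorted
#' draw), generates every slide via [generate_slide()] under per-slide
#' derived seeds, and draws clinical covariates and follow-up: event times
#' exponential with rate `log(2)/30 * exp(nuclear_effect)` for transforming
#' patients (capped at the horizon), administrative-horizon censoring for the
#' rest with early censoring at `censor_rate`. Slides of one patient share
#' the outcome. Optionally writes the on-disk bundle ([write_cohort_bundle()]).
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for the on-disk bundle.
#' @return List: `cohort` tibble (validated), `slides` named list of
#'   [generate_slide()] results, `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  n_oed <- n - config$n_controls
  n_events <- round(config$transform_fraction * n_oed)
  pat <- with_seed(derive_seed(config$seed, 0L), {
    draw <- runif(n_oed)
    transformed <- integer(n_oed)
    transformed[order(draw)[seq_len(n_events)]] <- 1L
    is_control <- c(rep(FALSE, n_oed), rep(TRUE, config$n_controls))
    tibble::tibble(
      patient_id = sprintf("pat%03d", seq_len(n)),
      is_control = is_control,
      transformed = c(transformed, rep(0L, config$n_controls)),
      age = round(rnorm(n, 60, 12)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      site = sample(c("tongue", "buccal_mucosa", "floor_of_mouth", "gingiva"),
                    n, replace = TRUE)
    )
  })

  rows <- list(); slides <- list()
  for (p in seq_len(n)) {
    for (s in seq_len(config$slides_per_patient)) {
      sid <- sprintf("%s_sl%d", pat$patient_id[p], s)
      outcome <- if (pat$is_control[p]) "control" else pat$transformed[p]
      slide <- generate_slide(config, outcome, slide_id = sid,
                              slide_seed = derive_seed(config$seed, p, s))
      slides[[sid]] <- slide
      clin <- with_seed(derive_seed(config$seed, p, s, 99L), {
        if (pat$is_control[p]) {
          list(fu = round(runif(1, 24, config$horizon_months), 1),
               who = NA_character_, bin = NA_character_)
        } else if (pat$transformed[p] == 1L) {
          t_ev <- rexp(1, rate = log(2) / 30 * exp(config$nuclear_effect))
          list(fu = round(min(max(t_ev, 1), config$horizon_months), 1),
               who = sample(c("mild", "moderate", "severe"), 1,
                            prob = c(0.2, 0.4, 0.4)),
               bin = sample(c("low_risk", "high_risk"), 1, prob = c(0.3, 0.7)))
        } else {
          fu <- if (runif(1) < config$censor_rate) {
            round(runif(1, 12, config$horizon_months), 1)
          } else config$horizon_months
          list(fu = fu,
               who = sample(c("mild", "moderate", "severe"), 1,
                            prob = c(0.5, 0.35, 0.15)),
               bin = sample(c("low_risk", "high_risk"), 1, prob = c(0.7, 0.3)))
        }
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slide_id = sid, patient_id = pat$patient_id[p],
        transformed = pat$transformed[p], follow_up_months = clin$fu,
        who_grade = clin$who, binary_grade = clin$bin,
        age = pat$age[p], sex = pat$sex[p], site = pat$site[p],
        cohort_tag = "internal", is_control = pat$is_control[p],
        dysplasia_fraction = slide$dysplasia_fraction
      )
    }
  }
  cohort <- validate_cohort(dplyr::bind_rows(rows))
  out <- list(cohort = cohort, slides = slides, config = config)
  if (!is.null(dir)) write_cohort_bundle(out, dir)
  out
}

#' Write a generated cohort to disk in the formats the readers consume
#'
#' Masks as PNG, nuclei as GeoJSON, the cohort as CSV, and a JSON manifest
#' of the generating parameters.
#'
#' @param bundle Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  for (sid in names(bundle$slides)) {
    sl <- bundle$slides[[sid]]
    write_mask(sl$epithelium, file.path(dir, sprintf("%s_epithelium.png", sid)))
    write_mask(sl$dysplasia, file.path(dir, sprintf("%s_dysplasia.png", sid)))
    write_nuclei(sl$nuclei, file.path(dir, sprintf("%s_nuclei.geojson", sid)))
  }
  cfg <- bundle$config
  cfg$densities <- as.list(cfg$densities)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
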