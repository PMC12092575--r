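COMPARTMENT_CLASSES <- c("dysplastic_epithelial", "normal_epithelial",
                         "iel", "pel")

#' Assign nuclear compartment classes
#'
#' Epithelial raw classes pass through unchanged. `other` nuclei are split by
#' the epithelium pixel under their centroid into intra-epithelial
#' lymphocytes (IEL, centroid on epithelium) and peri-epithelial lymphocytes
#' (PEL, centroid outside the epithelium). Centroids outside the mask bounds
#' are clipped to the border pixel.
#'
#' @param nuclei Nuclei tibble (see [read_nuclei()]).
#' @param epithelium Epithelium [mask_raster()] at the same resolution as the
#'   nucleus coordinates.
#' @return The tibble with a `compartment_class` column added.
#' @export
assign_compartment <- function(nuclei, epithelium) {
  if (nrow(nuclei) == 0) {
    return(dplyr::mutate(nuclei, compartment_class = character(0)))
  }
  inside <- mask_value_at(epithelium, nuclei$centroid_x, nuclei$centroid_y) == 1L
  comp <- dplyr::case_when(
    nuclei$raw_class != "other" ~ nuclei$raw_class,
    inside ~ "iel",
    TRUE ~ "pel"
  )
  dplyr::mutate(nuclei, compartment_class = comp)
}

#' The default feature registry
#'
#' Defines the ordered set of 168 per-patch nuclear features: for each of
#' the four compartment classes, count, density and mean/sd of the eight
#' morphometric measures (72 morphological features), plus 96 spatial
#' features (within- and cross-class nearest-neighbour distance statistics,
#' Clark-Evans aggregation indices, centroid dispersion, Delaunay graph
#' degree/edge-length statistics and class-mixing edge fractions, per-class
#' nuclear area fractions and patch tissue-composition fractions). The
#' registry is data: callers can substitute their own definition table and
#' feature order without code changes, as long as extraction emits the same
#' names.
#'
#' @return Tibble with columns `name`, `block`, `scope`.
#' @export
feature_registry <- function() {
  cls <- COMPARTMENT_CLASSES
  rows <- list()
  add <- function(name, block, scope) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(name = name, block = block,
                                                 scope = scope)
  }
  for (k in cls) {
    add(sprintf("%s_count", k), "morphological", k)
    add(sprintf("%s_density_mm2", k), "morphological", k)
    for (m in MORPHOMETRIC_NAMES) {
      add(sprintf("%s_%s_mean", k, m), "morphological", k)
      add(sprintf("%s_%s_sd", k, m), "morphological", k)
    }
  }
  for (k in cls) for (s in c("mean", "sd", "min"))
    add(sprintf("%s_nn1_%s", k, s), "spatial", k)
  for (k in cls) for (s in c("mean", "sd"))
    add(sprintf("%s_nn2_%s", k, s), "spatial", k)
  for (a in cls) for (b in setdiff(cls, a)) for (s in c("mean", "sd"))
    add(sprintf("xnn_%s_to_%s_%s", a, b, s), "spatial", "cross")
  for (s in c("mean", "sd", "min"))
    add(sprintf("all_nn1_%s", s), "spatial", "all")
  for (k in cls) add(sprintf("%s_clark_evans", k), "spatial", k)
  for (k in cls) add(sprintf("%s_centroid_dispersion_um", k), "spatial", k)
  for (k in cls) for (s in c("mean", "sd"))
    add(sprintf("%s_del_degree_%s", k, s), "spatial", k)
  for (k in cls) for (s in c("mean", "sd", "min"))
    add(sprintf("%s_del_edge_um_%s", k, s), "spatial", k)
  for (s in c("mean", "sd", "min"))
    add(sprintf("all_del_edge_um_%s", s), "spatial", "all")
  pairs <- c(lapply(cls, function(k) c(k, k)),
             combn(cls, 2, simplify = FALSE))
  for (p in pairs)
    add(sprintf("del_edge_frac_%s__%s", p[1], p[2]), "spatial", "cross")
  add("all_del_degree_mean", "spatial", "all")
  for (k in cls) add(sprintf("%s_area_fraction", k), "spatial", k)
  add("tissue_frac_dysplastic_epith", "spatial", "tissue")
  add("tissue_frac_normal_epith", "spatial", "tissue")
  add("tissue_frac_other", "spatial", "tissue")
  out <- dplyr::bind_rows(rows)
  stopifnot(nrow(out) == 168L, !anyDuplicated(out$name))
  out
}

#' Ordered names of the 168 default features
#' @return Character vector of length 168.
#' @export
feature_names <- function() feature_registry()$name

# Features for one half-open patch window. `nx`, `ny` are nucleus centroids
# in target-mpp pixels; morph is the 8-column morphometrics matrix (microns);
# comp the compartment class vector. Tissue fractions come from the
# epithelium/dysplasia pixel windows. Statistics over empty sets are imputed
# as 0 (class absence is recoverable from the count features). A patch with
# zero nuclei yields the all-zero vector.
patch_feature_vector <- function(nx, ny, comp, morph, ep_win, dy_win,
                                 patch_size, target_mpp) {
  nm <- feature_names()
  v <- stats::setNames(numeric(168L), nm)
  n <- length(nx)
  if (n == 0) return(v)

  cls <- COMPARTMENT_CLASSES
  patch_um <- patch_size * target_mpp
  patch_area_um2 <- patch_um^2
  patch_area_mm2 <- (patch_um / 1000)^2
  xu <- nx * target_mpp; yu <- ny * target_mpp  # microns, patch-local scale

  idx <- lapply(cls, function(k) which(comp == k))
  names(idx) <- cls

  for (k in cls) {
    i <- idx[[k]]
    v[sprintf("%s_count", k)] <- length(i)
    v[sprintf("%s_density_mm2", k)] <- length(i) / patch_area_mm2
    for (j in seq_along(MORPHOMETRIC_NAMES)) {
      m <- MORPHOMETRIC_NAMES[j]
      v[sprintf("%s_%s_mean", k, m)] <- mean0(morph[i, j])
      v[sprintf("%s_%s_sd", k, m)] <- sd0(morph[i, j])
    }
  }

  D <- as.matrix(stats::dist(cbind(xu, yu)))
  diag(D) <- Inf

  nn_stats <- function(i) {
    if (length(i) < 2) return(c(0, 0, 0, 0, 0))
    sub <- D[i, i, drop = FALSE]
    nn1 <- apply(sub, 1, min)
    nn2 <- if (length(i) >= 3) {
      apply(sub, 1, function(r) sort(r)[2])
    } else numeric(0)
    c(mean(nn1), sd0(nn1), min(nn1), mean0(nn2), sd0(nn2))
  }
  for (k in cls) {
    s <- nn_stats(idx[[k]])
    v[sprintf("%s_nn1_%s", k, c("mean", "sd", "min"))] <- s[1:3]
    v[sprintf("%s_nn2_%s", k, c("mean", "sd"))] <- s[4:5]
  }
  for (a in cls) for (b in setdiff(cls, a)) {
    ia <- idx[[a]]; ib <- idx[[b]]
    if (length(ia) > 0 && length(ib) > 0) {
      d <- apply(D[ia, ib, drop = FALSE], 1, min)
      v[sprintf("xnn_%s_to_%s_mean", a, b)] <- mean(d)
      v[sprintf("xnn_%s_to_%s_sd", a, b)] <- sd0(d)
    }
  }
  if (n >= 2) {
    nn1_all <- apply(D, 1, min)
    v["all_nn1_mean"] <- mean(nn1_all)
    v["all_nn1_sd"] <- sd0(nn1_all)
    v["all_nn1_min"] <- min(nn1_all)
  }
  for (k in cls) {
    i <- idx[[k]]
    if (length(i) >= 2) {
      nn1 <- apply(D[i, i, drop = FALSE], 1, min)
      # Clark-Evans R = observed mean NN / expected under CSR at the class
      # density within the patch
      v[sprintf("%s_clark_evans", k)] <-
        mean(nn1) / (0.5 / sqrt(length(i) / patch_area_um2))
      cxk <- mean(xu[i]); cyk <- mean(yu[i])
      v[sprintf("%s_centroid_dispersion_um", k)] <-
        sqrt(mean((xu[i] - cxk)^2 + (yu[i] - cyk)^2))
    }
  }

  dl <- delaunay_triangulate(xu, yu)
  edges <- dl$edges
  if (nrow(edges) > 0) {
    elen <- sqrt((xu[edges[, 1]] - xu[edges[, 2]])^2 +
                   (yu[edges[, 1]] - yu[edges[, 2]])^2)
    v["all_del_edge_um_mean"] <- mean(elen)
    v["all_del_edge_um_sd"] <- sd0(elen)
    v["all_del_edge_um_min"] <- min(elen)
    v["all_del_degree_mean"] <- mean(dl$degree)
    ecls <- cbind(comp[edges[, 1]], comp[edges[, 2]])
    for (k in cls) {
      i <- idx[[k]]
      if (length(i) > 0) {
        v[sprintf("%s_del_degree_mean", k)] <- mean(dl$degree[i])
        v[sprintf("%s_del_degree_sd", k)] <- sd0(dl$degree[i])
      }
      inc <- ecls[, 1] == k | ecls[, 2] == k
      v[sprintf("%s_del_edge_um_mean", k)] <- mean0(elen[inc])
      v[sprintf("%s_del_edge_um_sd", k)] <- sd0(elen[inc])
      v[sprintf("%s_del_edge_um_min", k)] <- min0(elen[inc])
    }
    pairs <- c(lapply(cls, function(k) c(k, k)), combn(cls, 2, simplify = FALSE))
    for (p in pairs) {
      hit <- (ecls[, 1] == p[1] & ecls[, 2] == p[2]) |
        (ecls[, 1] == p[2] & ecls[, 2] == p[1])
      v[sprintf("del_edge_frac_%s__%s", p[1], p[2])] <- mean(hit)
    }
  }

  area_col <- match("area_um2", MORPHOMETRIC_NAMES)
  for (k in cls) {
    v[sprintf("%s_area_fraction", k)] <-
      sum(morph[idx[[k]], area_col]) / patch_area_um2
  }

  npx <- length(ep_win)
  ep_dy <- sum(ep_win & dy_win)
  v["tissue_frac_dysplastic_epith"] <- ep_dy / npx
  v["tissue_frac_normal_epith"] <- (sum(ep_win) - ep_dy) / npx
  v["tissue_frac_other"] <- 1 - sum(ep_win) / npx
  v
}

#' Extract the 168-feature vector for every patch of a grid
#'
#' Nuclei are assigned to a patch iff their centroid lies in the half-open
#' window `[x, x+patch_size) x [y, y+patch_size)` (at the grid's target
#' resolution); with an overlapping grid a nucleus may legitimately
#' contribute to several patches. Empty patches yield an all-zero vector and
#' are flagged in the `n_nuclei` column. All values are finite.
#'
#' @param epithelium,dysplasia Co-registered [mask_raster()] objects.
#' @param nuclei Nuclei tibble with contours at the mask resolution.
#' @param grid A [make_patch_grid()] (typically after
#'   [filter_scoring_patches()]).
#' @return Tibble: `slide_id`, `patch_id`, `x`, `y`, `n_nuclei`, then the
#'   168 named feature columns.
#' @export
extract_features <- function(epithelium, dysplasia, nuclei, grid) {
  check_coregistered(epithelium, dysplasia)
  meta <- grid_meta(grid)
  ps <- meta$patch_size
  rescale <- meta$source_rescale
  nuclei <- assign_compartment(nuclei, epithelium)
  nuclei <- nuclei_morphometrics(nuclei, mpp = epithelium$mpp)
  morph <- as.matrix(nuclei[, MORPHOMETRIC_NAMES])
  tx <- nuclei$centroid_x * rescale
  ty <- nuclei$centroid_y * rescale
  ep_t <- rescale_mask(epithelium, rescale)
  dy_t <- rescale_mask(dysplasia, rescale)

  rows <- purrr::pmap(list(grid$patch_id, grid$x, grid$y), function(pid, x0, y0) {
    inpatch <- which(tx >= x0 & tx < x0 + ps & ty >= y0 & ty < y0 + ps)
    r <- (y0 + 1):min(y0 + ps, nrow(ep_t$pixels))
    cl <- (x0 + 1):min(x0 + ps, ncol(ep_t$pixels))
    v <- patch_feature_vector(
      tx[inpatch] - x0, ty[inpatch] - y0,
      nuclei$compartment_class[inpatch],
      morph[inpatch, , drop = FALSE],
      ep_t$pixels[r, cl], dy_t$pixels[r, cl],
      ps, meta$target_mpp
    )
    dplyr::bind_cols(
      tibble::tibble(slide_id = epithelium$slide_id, patch_id = pid,
                     x = x0, y = y0, n_nuclei = length(inpatch)),
      tibble::as_tibble(as.list(v))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- dplyr::bind_cols(
      tibble::tibble(slide_id = character(0), patch_id = character(0),
                     x = integer(0), y = integer(0), n_nuclei = integer(0)),
      tibble::as_tibble(as.list(stats::setNames(numeric(168), feature_names())))[0, ]
    )
  }
  drop_log(sum(out$n_nuclei == 0), "empty patches (all-zero feature vector)")
  out
}
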