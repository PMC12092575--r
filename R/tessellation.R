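#' Build a regular overlapping patch grid over a slide region
#'
#' Tessellates a region into fixed-size square patches at a target
#' resolution. The standard settings are 512 px patches with 184 px overlap
#' at 1.0 mpp for segmentation-style grids and 512 px with 256 px overlap at
#' 0.5 mpp for the scoring grid. Origins advance by `patch_size - overlap`;
#' whenever the stride grid would leave an uncovered margin, one final
#' origin per axis is shifted back so the last patch ends exactly at the
#' region boundary (no tissue is fabricated by padding). Regions smaller
#' than one patch yield a single origin at 0 with a logged warning
#' (`edge_padded` flag).
#'
#' Patches are half-open windows `[x, x + patch_size) x [y, y + patch_size)`
#' in 0-based target-mpp pixel coordinates.
#'
#' @param region_shape `c(height, width)` of the region in pixels at
#'   `mask_mpp`.
#' @param mask_mpp Resolution of the source masks (microns per pixel).
#' @param patch_size Patch side length in pixels at `target_mpp`.
#' @param overlap Overlap between adjacent patches in pixels.
#' @param target_mpp Resolution the grid lives at.
#' @return A `patch_grid` object: tibble of `patch_id`, `x`, `y` origins
#'   plus grid metadata attributes.
#' @export
make_patch_grid <- function(region_shape, mask_mpp, patch_size = 512L,
                            overlap = 256L, target_mpp = mask_mpp) {
  assert_that(overlap < patch_size, "`overlap` must be < `patch_size`")
  assert_that(all(region_shape > 0), "empty region")
  rescale <- mask_mpp / target_mpp
  dims <- pmax(1L, as.integer(round(region_shape * rescale)))
  h <- dims[1]; w <- dims[2]
  stride <- patch_size - overlap
  axis_origins <- function(extent) {
    if (extent <= patch_size) return(0L)
    o <- seq.int(0L, extent - patch_size, by = stride)
    if (max(o) + patch_size < extent) o <- c(o, extent - patch_size)
    unique(o)
  }
  xs <- axis_origins(w)
  ys <- axis_origins(h)
  edge_padded <- (w < patch_size) || (h < patch_size)
  if (edge_padded) {
    warn("region smaller than one patch at target mpp; single edge-padded patch",
         class = "odynr_grid_warning")
  }
  grid <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]  # row-major order
  out <- tibble::tibble(
    patch_id = sprintf("p_%d_%d", grid$x, grid$y),
    x = grid$x, y = grid$y
  )
  structure(out,
            class = c("patch_grid", class(out)),
            patch_size = as.integer(patch_size),
            overlap = as.integer(overlap),
            target_mpp = target_mpp,
            source_rescale = rescale,
            region_dims = dims,
            edge_padded = edge_padded)
}

grid_meta <- function(grid) {
  attributes(grid)[c("patch_size", "overlap", "target_mpp",
                     "source_rescale", "region_dims", "edge_padded")]
}

# Extract the pixel block of `mask` (at mask mpp) covered by the half-open
# patch window at target mpp. The mask is rescaled (nearest neighbour) to
# the grid's target resolution first; windows are clipped at the region
# border (only relevant for edge-padded grids).
patch_mask_window <- function(mask, grid, x, y) {
  meta <- grid_meta(grid)
  m <- rescale_mask(mask, meta$source_rescale)
  ps <- meta$patch_size
  rows <- (y + 1):min(y + ps, nrow(m$pixels))
  cols <- (x + 1):min(x + ps, ncol(m$pixels))
  m$pixels[rows, cols, drop = FALSE]
}

#' Restrict a scoring grid to patches covered by dysplasia
#'
#' Scoring uses tissue in the dysplastic regions alone: a patch is retained
#' when the fraction of its pixels labelled dysplastic is at least
#' `min_coverage` (default 0.5). Slides whose grid empties out are flagged
#' `"no dysplastic patches"` via the `attr(, "n_dropped_slides")` pathway of
#' callers and excluded from scoring, never silently scored.
#'
#' @param grid A [make_patch_grid()] result.
#' @param dysplasia Dysplasia [mask_raster()] of the slide.
#' @param min_coverage Minimum dysplastic pixel fraction in `[0, 1]`.
#' @return The filtered `patch_grid` with a `dysplastic_fraction` column.
#' @export
filter_scoring_patches <- function(grid, dysplasia, min_coverage = 0.5) {
  assert_that(min_coverage >= 0 && min_coverage <= 1,
              "`min_coverage` must be in [0, 1]")
  meta <- grid_meta(grid)
  m <- rescale_mask(dysplasia, meta$source_rescale)
  ps <- meta$patch_size
  frac <- purrr::map2_dbl(grid$x, grid$y, function(x, y) {
    rows <- (y + 1):min(y + ps, nrow(m$pixels))
    cols <- (x + 1):min(x + ps, ncol(m$pixels))
    sum(m$pixels[rows, cols]) / (ps * ps)
  })
  keep <- frac >= min_coverage & frac > 0
  out <- grid[keep, ]
  out$dysplastic_fraction <- frac[keep]
  attrs <- grid_meta(grid)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- class(grid)
  if (nrow(out) == 0) {
    drop_log(1, sprintf("slide with no dysplastic patches (min_coverage=%g)",
                        min_coverage))
  }
  out
}
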