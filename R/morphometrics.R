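# Polygon geometry primitives (x = column, y = row convention; vertices in
# pixel coordinates, stored as open rings).

poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_centroid <- function(p) {
  a <- poly_signed_area(p)
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

poly_perimeter <- function(p) {
  d <- p - p[c(2:nrow(p), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Central second moments of the polygon region (per unit area), via the
# standard shoelace moment formulas. Returns the 2x2 covariance of the
# uniform distribution over the polygon.
poly_covariance <- function(p) {
  a <- poly_signed_area(p)
  if (a < 0) { p <- p[rev(seq_len(nrow(p))), , drop = FALSE]; a <- -a }
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12        # integral of y^2 dA
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12        # integral of x^2 dA
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  matrix(c(iyy / a - cx^2, ixy / a - cx * cy,
           ixy / a - cx * cy, ixx / a - cy^2), 2, 2)
}

# O(n^2) proper-intersection test between non-adjacent edges.
poly_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

convex_hull <- function(p) {
  idx <- grDevices::chull(p[, 1], p[, 2])
  p[idx, , drop = FALSE]
}

MORPHOMETRIC_NAMES <- c("area_um2", "perimeter_um", "circularity",
                        "eccentricity", "major_axis_um", "minor_axis_um",
                        "solidity", "equiv_diameter_um")

#' Per-nucleus morphometric measures
#'
#' Computes the eight shape measures used by the feature registry for one
#' contour polygon: area (um^2), perimeter (um), circularity `4*pi*A/P^2`,
#' eccentricity and major/minor axis lengths of the moment-equivalent
#' ellipse, solidity (area / convex hull area) and equivalent circular
#' diameter. Pixel coordinates are converted to microns via `mpp`.
#' Self-intersecting contours are repaired by falling back to their convex
#' hull (counted in `attr(, "n_repaired")` when called through
#' [nuclei_morphometrics()]).
#'
#' @param contour n x 2 matrix of polygon vertices (pixels).
#' @param mpp Microns per pixel.
#' @return Named numeric vector of the 8 measures.
#' @export
nucleus_morphometrics <- function(contour, mpp = 1) {
  p <- close_ring(contour)
  assert_that(nrow(p) >= 3, "polygon needs >= 3 vertices")
  repaired <- FALSE
  if (poly_self_intersects(p)) {
    p <- convex_hull(p)
    repaired <- TRUE
  }
  a_px <- abs(poly_signed_area(p))
  per_px <- poly_perimeter(p)
  area <- a_px * mpp^2
  perim <- per_px * mpp
  circ <- if (per_px > 0) 4 * pi * a_px / per_px^2 else 0
  cv <- poly_covariance(p)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  # For an ellipse with semi-axes a >= b the region covariance eigenvalues
  # are a^2/4 and b^2/4, so axis lengths are 4*sqrt(lambda).
  major <- 4 * sqrt(ev[1]) * mpp
  minor <- 4 * sqrt(ev[2]) * mpp
  ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
  hull_a <- abs(poly_signed_area(convex_hull(p)))
  solidity <- if (hull_a > 0) a_px / hull_a else 0
  out <- c(area, perim, circ, ecc, major, minor, solidity,
           2 * sqrt(area / pi))
  names(out) <- MORPHOMETRIC_NAMES
  attr(out, "repaired") <- repaired
  out
}

#' Morphometrics for a nuclei table
#'
#' Vectorised wrapper over [nucleus_morphometrics()] returning one row per
#' nucleus, with the repair count for self-intersecting contours logged and
#' attached as `attr(, "n_repaired")`.
#'
#' @param nuclei Nuclei tibble (see [read_nuclei()]).
#' @param mpp Microns per pixel of the contour coordinates.
#' @return The input tibble with the 8 measure columns appended.
#' @export
nuclei_morphometrics <- function(nuclei, mpp = 1) {
  ms <- lapply(nuclei$contour, nucleus_morphometrics, mpp = mpp)
  n_rep <- sum(vapply(ms, function(m) isTRUE(attr(m, "repaired")), logical(1)))
  drop_log(n_rep, "self-intersecting contours repaired by convex hull")
  mtab <- tibble::as_tibble(do.call(rbind, c(ms, list(deparse.level = 0))))
  if (nrow(nuclei) == 0) {
    mtab <- tibble::as_tibble(matrix(numeric(0), 0, 8,
                                     dimnames = list(NULL, MORPHOMETRIC_NAMES)))
  }
  out <- dplyr::bind_cols(nuclei, mtab)
  attr(out, "n_repaired") <- n_rep
  out
}
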