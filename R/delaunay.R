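# Delaunay triangulation via incremental Bowyer-Watson insertion with a
# super-triangle. Adequate for the per-patch point counts used here (tens to
# a few hundred nuclei); validated in tests against the empty-circumcircle
# property. Near-degenerate (collinear) triangles get an effectively
# infinite circumcircle so they are always re-split.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) {
    return(c(Inf, Inf, Inf))
  }
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of a 2D point set
#'
#' @param x,y Point coordinates (equal length, no duplicates).
#' @return List with `triangles` (t x 3 index matrix), `edges` (m x 2 index
#'   matrix, each undirected edge once), and `degree` (per-point Delaunay
#'   neighbour count). For fewer than 3 points the triangle set is empty and
#'   the edge set is the complete graph on the points.
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) {
    edges <- if (n == 2) matrix(c(1L, 2L), 1) else matrix(integer(0), 0, 2)
    deg <- tabulate(edges, nbins = n)
    return(list(triangles = matrix(integer(0), 0, 3), edges = edges,
                degree = deg))
  }
  # normalise to the unit box for conditioning
  cx <- (min(x) + max(x)) / 2; cy <- (min(y) + max(y)) / 2
  scale <- max(max(x) - min(x), max(y) - min(y), 1e-9)
  px <- c((x - cx) / scale, c(0, -20, 20))
  py <- c((y - cy) / scale, c(30, -20, -20))
  sup <- n + 1:3

  cap <- max(64L, 4L * n)
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  alive <- logical(cap)
  add_at <- function(slot, v) {
    tri[slot, ] <<- v
    cc <- circumcircle(px[v[1]], py[v[1]], px[v[2]], py[v[2]],
                       px[v[3]], py[v[3]])
    ccx[slot] <<- cc[1]; ccy[slot] <<- cc[2]; cr2[slot] <<- cc[3]
    alive[slot] <<- TRUE
  }
  grow <- function(extra) {
    old <- length(alive)
    newcap <- old + max(extra, old)
    tri <<- rbind(tri, matrix(NA_integer_, newcap - old, 3))
    ccx <<- c(ccx, numeric(newcap - old)); ccy <<- c(ccy, numeric(newcap - old))
    cr2 <<- c(cr2, numeric(newcap - old)); alive <<- c(alive, logical(newcap - old))
  }
  add_at(1L, sup)

  for (i in seq_len(n)) {
    live_idx <- which(alive)
    inside <- (px[i] - ccx[live_idx])^2 + (py[i] - ccy[live_idx])^2 <=
      cr2[live_idx] * (1 + 1e-12) + 1e-14
    bad <- live_idx[inside]
    if (length(bad) == 0) next  # should not happen inside the super-triangle
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- e[, 1] * (n + 4) + e[, 2]
    cnt <- table(key)
    boundary <- e[key %in% as.numeric(names(cnt)[cnt == 1]), , drop = FALSE]
    alive[bad] <- FALSE
    free <- which(!alive)
    if (length(free) < nrow(boundary)) {
      grow(nrow(boundary))
      free <- which(!alive)
    }
    for (j in seq_len(nrow(boundary))) {
      add_at(free[j], c(boundary[j, 1], boundary[j, 2], i))
    }
  }

  keep <- which(alive)
  keep <- keep[rowSums(matrix(tri[keep, ] %in% sup, ncol = 3)) == 0]
  triangles <- tri[keep, , drop = FALSE]
  if (nrow(triangles) == 0) {
    # all points collinear: fall back to the path graph along the line
    o <- order(px[seq_len(n)], py[seq_len(n)])
    edges <- cbind(o[-n], o[-1])
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  } else {
    e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    edges <- unique(e)
  }
  list(triangles = triangles, edges = edges,
       degree = tabulate(edges, nbins = n))
}
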