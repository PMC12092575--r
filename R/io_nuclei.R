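#' Canonical nuclear classes and the class synonym map
#'
#' Nuclear instance files exported from annotation tools carry heterogeneous
#' class labels. They are normalised (case-insensitively) to the three raw
#' classes used throughout: `dysplastic_epithelial`, `normal_epithelial`,
#' `other`. The default synonym map ships as an editable JSON file in
#' `inst/extdata/class_synonyms.json`; pass a path to override it.
#'
#' @param path Optional path to a JSON object mapping label -> canonical class.
#' @return Named character vector mapping lower-case labels to canonical
#'   classes.
#' @export
class_synonym_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_synonyms.json", package = "odynr")
  }
  m <- unlist(jsonlite::read_json(path))
  stats::setNames(as.character(m), tolower(names(m)))
}

RAW_CLASSES <- c("dysplastic_epithelial", "normal_epithelial", "other")

normalise_classes <- function(labels, synonyms) {
  key <- tolower(trimws(labels))
  out <- ifelse(key %in% RAW_CLASSES, key, unname(synonyms[key]))
  bad <- unique(labels[is.na(out)])
  if (length(bad) > 0) {
    abort(sprintf("unknown nucleus class label(s): %s",
                  paste(bad, collapse = ", ")),
          class = "odynr_validation_error")
  }
  out
}

# Construct the nuclei tibble from parallel vectors plus a list of contour
# matrices (n x 2, columns x,y in pixel coordinates). Degenerate polygons
# (< 3 vertices or zero area) are dropped with a logged count.
nuclei_tibble <- function(nucleus_id, raw_class, contours) {
  keep <- vapply(contours, function(p) {
    is.matrix(p) && nrow(p) >= 3 && abs(poly_signed_area(p)) > 0
  }, logical(1))
  drop_log(sum(!keep), "degenerate nucleus polygons")
  contours <- lapply(contours[keep], close_ring)
  cen <- t(vapply(contours, poly_centroid, numeric(2)))
  out <- tibble::tibble(
    nucleus_id = as.character(nucleus_id[keep]),
    raw_class = raw_class[keep],
    centroid_x = if (nrow(cen)) cen[, 1] else numeric(0),
    centroid_y = if (nrow(cen)) cen[, 2] else numeric(0),
    contour = contours
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Drop a duplicated closing vertex; contours are stored open, treated closed.
close_ring <- function(p) {
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  unname(p)
}

#' Read nuclear instance annotations
#'
#' Supports two dialects: a GeoJSON `FeatureCollection` of `Polygon`
#' geometries with the class in `properties$classification$name` or
#' `properties$class` (the QuPath export convention), and a CSV with columns
#' `nucleus_id`, `class`, `wkt_contour` (a `POLYGON ((x y, ...))` string).
#' Class labels are normalised via [class_synonym_map()]; unknown labels are
#' a validation error. Degenerate polygons are dropped with a logged count
#' recoverable from `attr(, "n_dropped")`.
#'
#' @param path Annotation file.
#' @param dialect `"geojson"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @param synonyms Named synonym map, see [class_synonym_map()].
#' @return Tibble with columns `nucleus_id`, `raw_class`, `centroid_x`,
#'   `centroid_y` and a `contour` list-column of n x 2 matrices.
#' @export
read_nuclei <- function(path, dialect = NULL, synonyms = class_synonym_map()) {
  assert_that(file.exists(path), sprintf("nuclei file not found: %s", path),
              class = "odynr_io_error")
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      geojson = , json = "geojson", csv = "csv",
                      abort("cannot infer nuclei dialect from extension",
                            class = "odynr_format_error"))
  }
  if (dialect == "geojson") {
    gj <- jsonlite::read_json(path)
    feats <- gj$features %||% list()
    ids <- character(0); cls <- character(0); contours <- list()
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      if (!identical(f$geometry$type, "Polygon")) next
      ring <- f$geometry$coordinates[[1]]
      p <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
      lab <- f$properties$classification$name %||% f$properties$class
      ids <- c(ids, as.character(f$id %||% f$properties$nucleus_id %||% i))
      cls <- c(cls, as.character(lab))
      contours <- c(contours, list(p))
    }
    raw <- normalise_classes(cls, synonyms)
    nuclei_tibble(ids, raw, contours)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("nucleus_id", "class", "wkt_contour")
    assert_that(all(need %in% names(df)),
                sprintf("nuclei CSV must have columns: %s",
                        paste(need, collapse = ", ")),
                class = "odynr_format_error")
    contours <- lapply(df$wkt_contour, parse_wkt_polygon)
    raw <- normalise_classes(df$class, synonyms)
    nuclei_tibble(df$nucleus_id, raw, contours)
  }
}

#' Write nuclear instances
#'
#' Emits either the GeoJSON or the CSV/WKT dialect read by [read_nuclei()];
#' the two encodings round-trip to identical instance sets.
#'
#' @param nuclei Nuclei tibble (see [read_nuclei()]).
#' @param path Output path; dialect inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    feats <- purrr::pmap(
      list(nuclei$nucleus_id, nuclei$raw_class, nuclei$contour),
      function(id, cls, p) {
        ring <- lapply(seq_len(nrow(p) + 1), function(i) {
          j <- if (i > nrow(p)) 1L else i
          c(p[j, 1], p[j, 2])
        })
        list(type = "Feature", id = id,
             properties = list(classification = list(name = cls)),
             geometry = list(type = "Polygon", coordinates = list(ring)))
      })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- tibble::tibble(
      nucleus_id = nuclei$nucleus_id,
      class = nuclei$raw_class,
      wkt_contour = vapply(nuclei$contour, format_wkt_polygon, character(1))
    )
    readr::write_csv(df, path)
  } else {
    abort(sprintf("unsupported nuclei format: .%s", ext),
          class = "odynr_format_error")
  }
  invisible(path)
}

# Minimal WKT POLYGON support (single outer ring) for the CSV dialect.
parse_wkt_polygon <- function(s) {
  m <- regmatches(s, regexec("^\\s*POLYGON\\s*\\(\\(\\s*(.*?)\\s*\\)\\)\\s*$",
                             s, ignore.case = TRUE))[[1]]
  assert_that(length(m) == 2, sprintf("malformed WKT polygon: %s", substr(s, 1, 40)),
              class = "odynr_format_error")
  pairs <- strsplit(m[2], "\\s*,\\s*")[[1]]
  xy <- t(vapply(strsplit(pairs, "\\s+"), function(v) as.numeric(v[1:2]),
                 numeric(2)))
  close_ring(xy)
}

format_wkt_polygon <- function(p) {
  p <- rbind(p, p[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6g %.6g", p[, 1], p[, 2]), collapse = ", "))
}
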