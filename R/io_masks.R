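#' Binary label mask with physical resolution
#'
#' `mask_raster()` wraps a 2D integer label grid together with its isotropic
#' resolution in microns per pixel (mpp) and a slide identifier. It is the
#' contract for epithelium and dysplasia segmentation outputs consumed by the
#' downstream classification and scoring stages. Any nonzero input pixel is
#' coerced to 1 so that 255-valued PNG exports are handled transparently.
#'
#' Coordinate convention (used package-wide): x = column, y = row, both
#' 0-based, pixel centres at integer coordinates.
#'
#' @param pixels Integer matrix; nonzero entries mark the positive class.
#' @param mpp Microns per pixel, a single positive number.
#' @param slide_id Slide identifier string.
#' @return A `mask_raster` object.
#' @export
mask_raster <- function(pixels, mpp, slide_id = "slide") {
  assert_that(is.matrix(pixels), "`pixels` must be a matrix")
  assert_that(is.numeric(mpp) && length(mpp) == 1 && mpp > 0,
              "`mpp` must be a single positive number")
  px <- matrix(as.integer(pixels != 0), nrow = nrow(pixels))
  structure(
    list(pixels = px, mpp = as.numeric(mpp), slide_id = as.character(slide_id)),
    class = "mask_raster"
  )
}

#' @export
print.mask_raster <- function(x, ...) {
  cat(sprintf("<mask_raster> %s: %d x %d px @ %.4g mpp, %d positive\n",
              x$slide_id, nrow(x$pixels), ncol(x$pixels), x$mpp,
              sum(x$pixels)))
  invisible(x)
}

#' @export
dim.mask_raster <- function(x) dim(x$pixels)

#' Read a binary mask from a PNG or single-page TIFF file
#'
#' Single-channel images are binarized (any nonzero value maps to 1).
#' Multi-channel images are rejected unless all channels are identical,
#' because no binarization rule is declared for colour images.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @param mpp Microns per pixel to attach (not read from the file).
#' @param slide_id Slide identifier; defaults to the file stem.
#' @return A [mask_raster()].
#' @export
read_mask <- function(path, mpp, slide_id = NULL) {
  assert_that(file.exists(path), sprintf("mask file not found: %s", path),
              class = "odynr_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported mask format: .%s", ext), class = "odynr_format_error")
  )
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    same <- all(vapply(seq_len(ch), function(i) {
      identical(img[, , i], img[, , 1])
    }, logical(1)))
    if (!same) {
      abort("multi-channel colour mask without a declared binarization rule",
            class = "odynr_format_error")
    }
    img <- img[, , 1]
  }
  if (is.null(slide_id)) slide_id <- tools::file_path_sans_ext(basename(path))
  mask_raster(img != 0, mpp = mpp, slide_id = slide_id)
}

#' Write a binary mask to PNG or TIFF
#'
#' @param mask A [mask_raster()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_raster"))
  img <- mask$pixels * 1.0
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    abort(sprintf("unsupported mask format: .%s", ext), class = "odynr_format_error")
  )
  invisible(path)
}

#' Check that two masks of one slide are co-registered
#'
#' Epithelium and dysplasia masks of the same slide must share shape and
#' resolution; mismatches raise before any computation.
#'
#' @param a,b Two [mask_raster()] objects.
#' @return `TRUE`, invisibly.
#' @export
check_coregistered <- function(a, b) {
  stopifnot(inherits(a, "mask_raster"), inherits(b, "mask_raster"))
  assert_that(identical(dim(a$pixels), dim(b$pixels)),
              sprintf("masks not co-registered: %dx%d vs %dx%d",
                      nrow(a$pixels), ncol(a$pixels),
                      nrow(b$pixels), ncol(b$pixels)),
              class = "odynr_coregistration_error")
  assert_that(isTRUE(all.equal(a$mpp, b$mpp)),
              "masks not co-registered: mpp differs",
              class = "odynr_coregistration_error")
  invisible(TRUE)
}

# Mask value under a point (x = column, y = row, 0-based, pixel centres at
# integers). Points outside the grid are clipped to the border pixel.
mask_value_at <- function(mask, x, y) {
  px <- mask$pixels
  r <- pmin(pmax(round(y), 0), nrow(px) - 1L) + 1L
  c_ <- pmin(pmax(round(x), 0), ncol(px) - 1L) + 1L
  px[cbind(r, c_)]
}

# Nearest-neighbour rescale of a label mask by `factor` (target/source pixel
# count ratio). Labels stay categorical.
rescale_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "mask_raster"), factor > 0)
  if (isTRUE(all.equal(factor, 1))) return(mask)
  src <- mask$pixels
  nr <- max(1L, as.integer(round(nrow(src) * factor)))
  nc <- max(1L, as.integer(round(ncol(src) * factor)))
  ri <- pmin(nrow(src), pmax(1L, as.integer(floor((seq_len(nr) - 0.5) / factor)) + 1L))
  ci <- pmin(ncol(src), pmax(1L, as.integer(floor((seq_len(nc) - 0.5) / factor)) + 1L))
  mask_raster(src[ri, ci, drop = FALSE], mpp = mask$mpp / factor,
              slide_id = mask$slide_id)
}
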