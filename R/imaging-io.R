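## Reading, preprocessing and writing FA frames and masks.
##
## Preprocessing contract: optional banner crop first, then an anisotropic
## order-0 (nearest-neighbour, no anti-aliasing) rescale to 496 x 496, 8-bit.
## Nearest-neighbour is the only order under which a binary mask survives
## rescaling with no new gray levels, and preprocessing an already-conformant
## image is a bit-exact no-op.

.readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF): ", path))
  if (length(dim(raw)) == 3) {
    ## RGB(A)-encoded grayscale export: collapse by channel average
    raw <- (raw[, , 1] + raw[, , 2] + raw[, , 3]) / 3
  }
  if (!is.matrix(raw)) stop("file did not decode to a 2-D raster: ", path)
  raw
}

#' Preprocess a raw intensity matrix to the canonical FA grid
#'
#' @param mat numeric matrix of intensities in \[0, 255\].
#' @param crop optional banner crop `c(x, y, w, h)` (0-based top-left corner,
#'   width, height) applied before rescaling.
#' @param size output side length (default 496).
#' @return numeric matrix `size x size` of 8-bit intensities.
#' @export
preprocessImage <- function(mat, crop = NULL, size = FA_SIZE) {
  stopifnot(is.matrix(mat))
  if (!is.null(crop)) {
    crop <- as.numeric(crop)
    if (length(crop) != 4) stop("crop must be c(x, y, w, h)")
    x <- crop[1]; y <- crop[2]; w <- crop[3]; h <- crop[4]
    if (w <= 0 || h <= 0) stop("zero-area crop rejected")
    if (x < 0 || y < 0 || x + w > ncol(mat) || y + h > nrow(mat))
      stop("crop rectangle exceeds the image")
    mat <- mat[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
  }
  round(resizeNearest(mat, size, size))
}

#' Load an FA image file and apply the preprocessing contract
#'
#' Reads PNG/TIFF (RGB collapsed by channel average), applies the optional
#' banner crop, rescales anisotropically to 496 x 496 with nearest-neighbour
#' sampling (no anti-aliasing), and quantizes to 8 bits. A file already at
#' 496 x 496 and 8 bits passes through bit-identically.
#'
#' @param path image file path (PNG or TIFF).
#' @param crop optional `c(x, y, w, h)` banner crop, 0-based.
#' @param size output side length (default 496).
#' @return an [FAImage-class].
#' @export
readFAImage <- function(path, crop = NULL, size = FA_SIZE) {
  raw <- .readRaster(path) * 255
  FAImage(preprocessImage(raw, crop, size), source = normalizePath(path))
}

#' Write an FA image as 8-bit grayscale PNG or TIFF
#' @param image an [FAImage-class] (or numeric matrix in \[0, 255\]).
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeFAImage <- function(image, path) {
  m <- if (is(image, "FAImage")) pixels(image) else round(image)
  m <- clipRange(m, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'"))
  invisible(path)
}

#' Read a binary abnormal-region mask from a 0/1 image file
#'
#' Any strictly positive pixel is treated as abnormal (accepts both 0/1 and
#' 0/255 encodings).
#' @param path PNG or TIFF path.
#' @param source provenance tag (default "annotation_file").
#' @param size canonical side length; masks not on the canonical grid are
#'   nearest-neighbour rescaled (binarity preserved).
#' @return a [RegionMask-class].
#' @export
readRegionMask <- function(path, source = "annotation_file", size = FA_SIZE) {
  raw <- .readRaster(path)
  m <- resizeNearest(matrix(as.numeric(raw > 0), nrow(raw), ncol(raw)),
                     size, size)
  RegionMask(m, source = source)
}

#' Write a binary mask as a 0/1 PNG
#' @param mask a [RegionMask-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeRegionMask <- function(mask, path) {
  png::writePNG(pixels(mask), path)
  invisible(path)
}

#' Write a corrected (ratio-unit) image as 32-bit float TIFF
#' @param corrected a [CorrectedImage-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeCorrectedImage <- function(corrected, path) {
  ## 32-bit float sample format preserves ratio units exactly
  tiff::writeTIFF(pixels(corrected) / max(pixels(corrected), 1),
                  path, bits.per.sample = 32L)
  invisible(path)
}
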