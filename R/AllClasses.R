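#' @import methods
NULL

#' Canonical FA frame size (pixels per side)
#'
#' All clinical input images are preprocessed to this square size; synthetic
#' scenes may use smaller grids for speed, the pipeline is size-agnostic.
#' @export
FA_SIZE <- 496L

.checkBinary <- function(m, what) {
  if (!is.matrix(m)) return(sprintf("%s must be a matrix", what))
  if (length(m) && !all(m %in% c(0, 1)))
    return(sprintf("%s must contain only 0/1 values", what))
  NULL
}

.checkValid <- function(pixels, valid) {
  if (!is.matrix(valid) || !identical(dim(valid), dim(pixels)))
    return("'valid' must be a logical matrix with the same dimensions as 'pixels'")
  if (!is.logical(valid)) return("'valid' must be logical")
  NULL
}

#' FAImage: an 8-bit grayscale fundus fluorescein-angiography frame
#'
#' Pixels are stored as a numeric matrix of integers in \[0, 255\], row-major
#' with the origin at the top-left; pixel (x, y) uses 0-based coordinates so
#' that `pixels[y + 1, x + 1]` is the intensity at (x, y). The `valid` slot
#' flags pixels that carry real signal; warping marks out-of-frame pixels
#' invalid and every downstream stage (mode estimation, binarization,
#' scoring) honours the flag.
#'
#' @slot pixels numeric matrix of 8-bit intensities.
#' @slot valid logical matrix, same shape; FALSE marks out-of-frame pixels.
#' @slot source character, provenance (file path or "synthetic").
#' @slot metadata list of optional provenance fields (e.g. the generating
#'   [SyntheticScene-class] under `$scene`, capture phase in seconds).
#' @export
setClass("FAImage",
  representation(pixels = "matrix", valid = "matrix",
                 source = "character", metadata = "list"),
  prototype(source = "", metadata = list()))

setValidity("FAImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (length(p) && (min(p) < 0 || max(p) > 255))
    return("pixel intensities must lie in [0, 255]")
  if (length(p) && any(p != round(p)))
    return("pixel intensities must be integers (8-bit quantized)")
  err <- .checkValid(p, object@valid)
  if (!is.null(err)) return(err)
  TRUE
})

#' Constructor for [FAImage-class]
#'
#' @param pixels numeric matrix in \[0, 255\] (rounded to integers).
#' @param source provenance string.
#' @param valid optional logical matrix; defaults to all-TRUE.
#' @param metadata optional list.
#' @return an `FAImage`.
#' @export
FAImage <- function(pixels, source = "", valid = NULL, metadata = list()) {
  pixels <- round(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("FAImage", pixels = pixels, valid = valid, source = source,
      metadata = metadata)
}

#' RegionMask: binary abnormal-region mask
#'
#' Value 1 marks pixels predicted (or annotated) as belonging to the abnormal
#' region; 0 marks everything else. Shares the grid convention of
#' [FAImage-class].
#'
#' @slot pixels numeric 0/1 matrix.
#' @slot valid logical matrix (out-of-frame flags after warping).
#' @slot source one of "model", "annotation_file", "synthetic_truth".
#' @slot probThreshold probability cutoff used when `source == "model"`,
#'   otherwise `NA`.
#' @export
setClass("RegionMask",
  representation(pixels = "matrix", valid = "matrix",
                 source = "character", probThreshold = "numeric"),
  prototype(source = "annotation_file", probThreshold = NA_real_))

setValidity("RegionMask", function(object) {
  err <- .checkBinary(object@pixels, "mask pixels")
  if (!is.null(err)) return(err)
  err <- .checkValid(object@pixels, object@valid)
  if (!is.null(err)) return(err)
  if (!object@source %in% c("model", "annotation_file", "synthetic_truth"))
    return("source must be 'model', 'annotation_file' or 'synthetic_truth'")
  TRUE
})

#' Constructor for [RegionMask-class]
#' @param pixels 0/1 matrix (logical accepted).
#' @param source provenance enum.
#' @param valid optional logical matrix.
#' @param probThreshold probability cutoff for model-derived masks.
#' @return a `RegionMask`.
#' @export
RegionMask <- function(pixels, source = "annotation_file", valid = NULL,
                       probThreshold = NA_real_) {
  pixels <- matrix(as.numeric(pixels != 0), nrow(pixels), ncol(pixels))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("RegionMask", pixels = pixels, valid = valid, source = source,
      probThreshold = probThreshold)
}

#' CorrectedImage: background-flattened FA frame in ratio units
#'
#' Result of dividing an image by its Gaussian-blurred background; values
#' hover around 1.0 (= local background), hyperfluorescent structure sits
#' above it.
#'
#' @slot pixels non-negative numeric matrix (ratio units).
#' @slot valid logical matrix.
#' @slot sigma Gaussian sigma (pixels) used for the background estimate.
#' @slot source provenance of the parent image.
#' @export
setClass("CorrectedImage",
  representation(pixels = "matrix", valid = "matrix",
                 sigma = "numeric", source = "character"),
  prototype(sigma = 70, source = ""))

setValidity("CorrectedImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (length(p) && (!all(is.finite(p)) || min(p) < 0))
    return("corrected values must be finite and >= 0")
  err <- .checkValid(p, object@valid)
  if (!is.null(err)) return(err)
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' BinarizedImage: mode-thresholded hyperfluorescence map
#'
#' @slot pixels 0/1 matrix; 1 iff the corrected value exceeds
#'   `multiplier * modeValue` (strict) at a valid pixel.
#' @slot valid logical matrix.
#' @slot modeValue mode of the corrected image (256-bin histogram).
#' @slot thresholdValue `multiplier * modeValue`.
#' @slot multiplier threshold multiplier (default 1.2).
#' @export
setClass("BinarizedImage",
  representation(pixels = "matrix", valid = "matrix", modeValue = "numeric",
                 thresholdValue = "numeric", multiplier = "numeric"))

setValidity("BinarizedImage", function(object) {
  err <- .checkBinary(object@pixels, "binarized pixels")
  if (!is.null(err)) return(err)
  err <- .checkValid(object@pixels, object@valid)
  if (!is.null(err)) return(err)
  if (!isTRUE(all.equal(object@thresholdValue,
                        object@multiplier * object@modeValue)))
    return("thresholdValue must equal multiplier * modeValue")
  TRUE
})

#' AffineParams: 2x3 affine transform aligned -> reference
#'
#' The matrix `[a b tx; c d ty]` maps 0-based aligned-image coordinates
#' (x, y) to reference coordinates. Estimated transforms carry RANSAC
#' bookkeeping (`inlierCount`, `nCandidates`).
#'
#' @slot matrix numeric 2x3 matrix.
#' @slot inlierCount RANSAC inliers supporting the estimate (NA if exact).
#' @slot nCandidates number of candidate correspondences considered.
#' @export
setClass("AffineParams",
  representation(matrix = "matrix", inlierCount = "integer",
                 nCandidates = "integer"),
  prototype(inlierCount = NA_integer_, nCandidates = NA_integer_))

setValidity("AffineParams", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(2L, 3L)))
    return("matrix must be numeric 2x3")
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(dt) || dt < 0.5 || dt > 2.0)
    return(sprintf("determinant of the linear part (%.3f) outside [0.5, 2.0]", dt))
  TRUE
})

#' Constructor for [AffineParams-class]
#' @param matrix numeric 2x3 matrix `[a b tx; c d ty]`.
#' @param inlierCount,nCandidates RANSAC bookkeeping (optional).
#' @return an `AffineParams`.
#' @export
AffineParams <- function(matrix, inlierCount = NA_integer_,
                         nCandidates = NA_integer_) {
  new("AffineParams", matrix = matrix,
      inlierCount = as.integer(inlierCount),
      nCandidates = as.integer(nCandidates))
}

#' CorrespondenceSet: matched point pairs between two frames
#'
#' @slot reference n x 2 matrix of (x, y) points in the reference frame.
#' @slot aligned n x 2 matrix of the matching points in the aligned frame.
#' @slot source "automatic" (FAST/BRIEF) or "csv_file".
#' @export
setClass("CorrespondenceSet",
  representation(reference = "matrix", aligned = "matrix",
                 source = "character"),
  prototype(source = "automatic"))

setValidity("CorrespondenceSet", function(object) {
  if (ncol(object@reference) != 2 || ncol(object@aligned) != 2)
    return("point matrices must have two columns (x, y)")
  if (nrow(object@reference) != nrow(object@aligned))
    return("reference and aligned point counts differ")
  if (!object@source %in% c("automatic", "csv_file"))
    return("source must be 'automatic' or 'csv_file'")
  TRUE
})

#' ScoreReport: result of scoring an FA image pair
#'
#' @slot referenceScore hyperfluorescent pixel count of the reference image.
#' @slot testScore hyperfluorescent pixel count of the aligned/test image.
#' @slot mergedMaskArea pixel count of the merged (OR) abnormal-region mask
#'   restricted to mutually valid pixels.
#' @slot growthRate `(testScore - referenceScore) / referenceScore`; `NA`
#'   when the reference score is zero (undefined, never infinite).
#' @slot maskSources provenance of the two masks (reference, test).
#' @slot details list: mode values, thresholds, transform, validity counts.
#' @export
setClass("ScoreReport",
  representation(referenceScore = "numeric", testScore = "numeric",
                 mergedMaskArea = "numeric", growthRate = "numeric",
                 maskSources = "character", details = "list"),
  prototype(details = list()))

setValidity("ScoreReport", function(object) {
  if (object@referenceScore < 0 || object@testScore < 0)
    return("scores must be non-negative")
  if (max(object@referenceScore, object@testScore) > object@mergedMaskArea)
    return("scores cannot exceed the merged mask area")
  if (object@referenceScore > 0) {
    g <- (object@testScore - object@referenceScore) / object@referenceScore
    if (!isTRUE(all.equal(g, object@growthRate)))
      return("growthRate inconsistent with the two scores")
  } else if (!is.na(object@growthRate)) {
    return("growthRate must be NA when the reference score is zero")
  }
  TRUE
})

#' SyntheticScene: ground-truth decomposition of a synthetic FA frame
#'
#' Holds every layer the renderer composes, so downstream stages can be
#' checked against exact truth: vessel tree, lesion blob(s) (= the true
#' abnormal region), speckled mottle inside the lesion, and a smooth
#' multiplicative illumination field.
#'
#' @slot width,height grid size in pixels.
#' @slot vesselMap,lesionMask,mottleMap 0/1 matrices; `mottleMap` is a subset
#'   of `lesionMask | vesselMap`.
#' @slot illumination positive numeric matrix, low-frequency only.
#' @slot baseIntensity background 8-bit level.
#' @slot lesionGain,vesselGain,mottleGain additive 8-bit gains of the layers.
#' @slot seed integer RNG seed the scene was drawn from.
#' @export
setClass("SyntheticScene",
  representation(width = "integer", height = "integer",
                 vesselMap = "matrix", lesionMask = "matrix",
                 mottleMap = "matrix", illumination = "matrix",
                 baseIntensity = "numeric", lesionGain = "numeric",
                 vesselGain = "numeric", mottleGain = "numeric",
                 seed = "integer"))

setValidity("SyntheticScene", function(object) {
  d <- c(object@height, object@width)
  for (nm in c("vesselMap", "lesionMask", "mottleMap", "illumination"))
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("%s dimensions disagree with width/height", nm))
  for (nm in c("vesselMap", "lesionMask", "mottleMap")) {
    err <- .checkBinary(slot(object, nm), nm)
    if (!is.null(err)) return(err)
  }
  stray <- object@mottleMap == 1 & !(object@lesionMask == 1 | object@vesselMap == 1)
  if (any(stray))
    return("mottleMap must be a subset of lesionMask | vesselMap")
  if (min(object@illumination) <= 0)
    return("illumination must be strictly positive everywhere")
  TRUE
})

#' SegmenterModel: trained abnormal-region segmentation network
#'
#' An encoder-decoder network with skip connections (U-net family),
#' implemented natively; inference is deterministic given the weights.
#'
#' @slot weights list of convolution weight/bias arrays per layer.
#' @slot config training configuration (see [segmenterConfig()]).
#' @slot trainingLoss numeric vector of per-epoch mean training losses.
#' @export
setClass("SegmenterModel",
  representation(weights = "list", config = "list", trainingLoss = "numeric"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "FAImage", function(object) {
  cat(sprintf("FAImage %dx%d [%d, %d], %d/%d valid, source='%s'\n",
              nrow(object@pixels), ncol(object@pixels),
              if (length(object@pixels)) min(object@pixels) else NA,
              if (length(object@pixels)) max(object@pixels) else NA,
              sum(object@valid), length(object@valid), object@source))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask %dx%d, area=%d px, source='%s'\n",
              nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels == 1), object@source))
})

setMethod("show", "CorrectedImage", function(object) {
  cat(sprintf("CorrectedImage %dx%d (ratio units), sigma=%g px, mean=%.3f\n",
              nrow(object@pixels), ncol(object@pixels), object@sigma,
              mean(object@pixels[object@valid])))
})

setMethod("show", "BinarizedImage", function(object) {
  cat(sprintf("BinarizedImage %dx%d, %d px above %.4f (= %.2f x mode %.4f)\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              object@thresholdValue, object@multiplier, object@modeValue))
})

setMethod("show", "AffineParams", function(object) {
  m <- object@matrix
  cat(sprintf("AffineParams [%.4f %.4f %8.3f; %.4f %.4f %8.3f]",
              m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3]))
  if (!is.na(object@inlierCount))
    cat(sprintf("  (%d/%d inliers)", object@inlierCount, object@nCandidates))
  cat("\n")
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet: %d pairs, source='%s'\n",
              nrow(object@reference), object@source))
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport\n")
  cat(sprintf("  Reference score : %d\n", as.integer(object@referenceScore)))
  cat(sprintf("  Test score      : %d\n", as.integer(object@testScore)))
  cat(sprintf("  Merged mask area: %d\n", as.integer(object@mergedMaskArea)))
  cat(sprintf("  Growth rate     : %s\n",
              if (is.na(object@growthRate)) "undefined (reference score 0)"
              else sprintf("%.4f", object@growthRate)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene %dx%d, seed=%d: lesion %d px, vessel %d px, mottle %d px\n",
    object@width, object@height, object@seed,
    sum(object@lesionMask), sum(object@vesselMap), sum(object@mottleMap)))
})

setMethod("show", "SegmenterModel", function(object) {
  cat(sprintf(
    "SegmenterModel: depth %d, base %d channels, %d epochs (final loss %.4f)\n",
    object@config$depth, object@config$baseChannels,
    length(object@trainingLoss),
    if (length(object@trainingLoss)) tail(object@trainingLoss, 1) else NA))
})
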