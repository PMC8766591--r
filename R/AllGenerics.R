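#' Pixel matrix of an image-like object
#' @param x an image-like S4 object.
#' @return numeric matrix of pixel values.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Validity (in-frame) mask of an image-like object
#' @param x an image-like S4 object.
#' @return logical matrix; FALSE marks pixels invalidated by warping.
#' @export
setGeneric("validPixels", function(x) standardGeneric("validPixels"))

#' Apply an affine transform, resampling onto the reference grid
#'
#' `params` maps aligned-image coordinates to reference coordinates; the
#' result is the input resampled on the reference grid (inverse mapping).
#' FA images are interpolated bilinearly, masks with nearest-neighbour so
#' they stay binary. Out-of-frame pixels are filled with 0 and flagged
#' invalid.
#'
#' @param x an [FAImage-class] or [RegionMask-class].
#' @param params an [AffineParams-class].
#' @param ... unused.
#' @return an object of the same class as `x`.
#' @export
setGeneric("applyAffine", function(x, params, ...) standardGeneric("applyAffine"))

#' @describeIn pixels for FAImage
#' @export
setMethod("pixels", "FAImage", function(x) x@pixels)
#' @describeIn pixels for RegionMask
#' @export
setMethod("pixels", "RegionMask", function(x) x@pixels)
#' @describeIn pixels for CorrectedImage
#' @export
setMethod("pixels", "CorrectedImage", function(x) x@pixels)
#' @describeIn pixels for BinarizedImage
#' @export
setMethod("pixels", "BinarizedImage", function(x) x@pixels)

#' @describeIn validPixels for FAImage
#' @export
setMethod("validPixels", "FAImage", function(x) x@valid)
#' @describeIn validPixels for RegionMask
#' @export
setMethod("validPixels", "RegionMask", function(x) x@valid)
#' @describeIn validPixels for CorrectedImage
#' @export
setMethod("validPixels", "CorrectedImage", function(x) x@valid)
#' @describeIn validPixels for BinarizedImage
#' @export
setMethod("validPixels", "BinarizedImage", function(x) x@valid)

#' Accessors for ScoreReport
#' @param x a [ScoreReport-class].
#' @return numeric scalar.
#' @name score-accessors
NULL

#' @rdname score-accessors
#' @export
setGeneric("referenceScore", function(x) standardGeneric("referenceScore"))
#' @rdname score-accessors
#' @export
setGeneric("testScore", function(x) standardGeneric("testScore"))
#' @rdname score-accessors
#' @export
setGeneric("mergedMaskArea", function(x) standardGeneric("mergedMaskArea"))
#' @rdname score-accessors
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname score-accessors
#' @export
setMethod("referenceScore", "ScoreReport", function(x) x@referenceScore)
#' @rdname score-accessors
#' @export
setMethod("testScore", "ScoreReport", function(x) x@testScore)
#' @rdname score-accessors
#' @export
setMethod("mergedMaskArea", "ScoreReport", function(x) x@mergedMaskArea)
#' @rdname score-accessors
#' @export
setMethod("growthRate", "ScoreReport", function(x) x@growthRate)
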