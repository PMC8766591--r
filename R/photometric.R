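## Photometric normalization: Gaussian-background division removes the
## low-frequency luminance slope; histogram matching equalizes the pair so
## the two mode-threshold binarizations are comparable.

#' Flatten the luminance slope by Gaussian background division
#'
#' Estimates the background as the sigma = 70 px Gaussian blur of the image
#' (reflected boundaries) and divides the image by it, guarding against zero
#' division. The result is in ratio units: ~1.0 equals the local background,
#' hyperfluorescent structure sits above it. Multiplying the input by any
#' smooth field with features much broader than sigma leaves the output
#' essentially unchanged - the operation's entire purpose.
#'
#' @param image an [FAImage-class] (or numeric matrix).
#' @param sigma Gaussian standard deviation in pixels (default 70).
#' @param valid optional logical matrix overriding the image's validity mask.
#' @return a [CorrectedImage-class].
#' @export
flattenBackground <- function(image, sigma = 70, valid = NULL) {
  isFA <- is(image, "FAImage")
  x <- if (isFA) pixels(image) else image
  if (is.null(valid)) valid <- if (isFA) validPixels(image)
                               else matrix(TRUE, nrow(x), ncol(x))
  src <- if (isFA) image@source else ""
  if (max(x) <= 0) {
    warning("all-zero image: corrected image is all zero")
    return(new("CorrectedImage", pixels = x * 0, valid = valid,
               sigma = sigma, source = src))
  }
  bg <- gaussianBlurReflect(x, sigma)
  eps <- 1e-6 * max(x)
  out <- x / pmax(bg, eps)
  out[!valid] <- 0
  new("CorrectedImage", pixels = out, valid = valid, sigma = sigma,
      source = src)
}

#' Match the intensity distribution of a test image to a reference
#'
#' Histogram specification on a 256-bin quantization of the ratio images:
#' each test bin is remapped to the reference bin whose cumulative frequency
#' first reaches the test bin's cumulative frequency. The remap is monotone
#' (pixel ranks preserved up to quantization) and the reference is never
#' modified. Only mutually valid pixels enter the histograms.
#'
#' @param test the [CorrectedImage-class] to remap (the Aligned image).
#' @param reference the fixed standard [CorrectedImage-class].
#' @param nbins histogram resolution (256).
#' @return the remapped test image as a [CorrectedImage-class].
#' @export
matchHistogram <- function(test, reference, nbins = 256) {
  stopifnot(is(test, "CorrectedImage"), is(reference, "CorrectedImage"),
            identical(dim(pixels(test)), dim(pixels(reference))))
  tv <- pixels(test); rv <- pixels(reference)
  vmask <- validPixels(test) & validPixels(reference)
  tvv <- tv[vmask]; rvv <- rv[vmask]
  out <- tv
  rRange <- range(rvv)
  if (diff(rRange) == 0) {
    warning("constant reference: test image mapped to that constant")
    out[vmask] <- rRange[1]
  } else if (diff(range(tvv)) == 0) {
    ## constant test: maps to the reference median bin
    rBreaks <- seq(rRange[1], rRange[2], length.out = nbins + 1)
    rCdf <- cumsum(tabulate(findInterval(rvv, rBreaks, all.inside = TRUE),
                            nbins)) / length(rvv)
    rCenters <- (rBreaks[-1] + rBreaks[-(nbins + 1)]) / 2
    out[vmask] <- rCenters[which(rCdf >= 0.5)[1]]
  } else {
    tRange <- range(tvv)
    tBreaks <- seq(tRange[1], tRange[2], length.out = nbins + 1)
    rBreaks <- seq(rRange[1], rRange[2], length.out = nbins + 1)
    tBin <- findInterval(tvv, tBreaks, all.inside = TRUE)
    tCdf <- cumsum(tabulate(tBin, nbins)) / length(tvv)
    rCdf <- cumsum(tabulate(findInterval(rvv, rBreaks, all.inside = TRUE),
                            nbins)) / length(rvv)
    rCenters <- (rBreaks[-1] + rBreaks[-(nbins + 1)]) / 2
    ## monotone lookup: first reference bin whose CDF >= test bin CDF
    map <- rCenters[pmin(findInterval(tCdf, rCdf, left.open = TRUE) + 1, nbins)]
    out[vmask] <- map[tBin]
  }
  out[!vmask] <- 0
  new("CorrectedImage", pixels = pmax(out, 0), valid = vmask,
      sigma = test@sigma, source = test@source)
}
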