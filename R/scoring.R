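## Mode-threshold binarization, mask merging and Score / Growth-rate
## computation. The Score is the count of hyperfluorescent pixels (corrected
## value strictly above 1.2x the mode) inside the merged abnormal-region
## mask; the Growth rate is (Test score - Reference score) / Reference score.

#' Mode of a corrected image by 256-bin histogram
#'
#' Valid pixels are quantized into `nbins` uniform bins over their observed
#' range; the mode is the centre of the most populated bin, ties broken
#' toward the lower bin.
#' @param corrected a [CorrectedImage-class] (or numeric matrix).
#' @param valid optional logical matrix restricting the pixels considered.
#' @param nbins histogram resolution (256).
#' @return the mode as a numeric scalar.
#' @export
computeMode <- function(corrected, valid = NULL, nbins = 256) {
  x <- if (is(corrected, "CorrectedImage")) pixels(corrected) else corrected
  if (is.null(valid))
    valid <- if (is(corrected, "CorrectedImage")) validPixels(corrected)
             else matrix(TRUE, nrow(x), ncol(x))
  v <- x[valid]
  if (!length(v)) stop("no valid pixels: mode undefined")
  rg <- range(v)
  if (diff(rg) == 0) return(rg[1])
  breaks <- seq(rg[1], rg[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins)
  i <- which.max(counts)  # which.max returns the first (lower) maximal bin
  (breaks[i] + breaks[i + 1]) / 2
}

#' Binarize a corrected image at a multiple of its mode
#'
#' A pixel is hyperfluorescent iff its corrected value is strictly greater
#' than `multiplier * mode`; invalid pixels are forced to 0 and excluded
#' from the mode.
#' @param corrected a [CorrectedImage-class].
#' @param multiplier threshold multiplier (default 1.2).
#' @param valid optional logical matrix overriding the stored validity.
#' @param modeWithin optional [RegionMask-class]: compute the mode inside
#'   this mask only (off by default; the mode is taken over the whole valid
#'   image).
#' @param nbins histogram resolution for the mode (256).
#' @return a [BinarizedImage-class].
#' @export
binarizeImage <- function(corrected, multiplier = 1.2, valid = NULL,
                          modeWithin = NULL, nbins = 256) {
  stopifnot(is(corrected, "CorrectedImage"))
  if (is.null(valid)) valid <- validPixels(corrected)
  modeMask <- valid
  if (!is.null(modeWithin)) modeMask <- valid & pixels(modeWithin) == 1
  m <- computeMode(pixels(corrected), valid = modeMask, nbins = nbins)
  thr <- multiplier * m
  b <- (pixels(corrected) > thr) & valid
  new("BinarizedImage", pixels = matrix(as.numeric(b), nrow(b), ncol(b)),
      valid = valid, modeValue = m, thresholdValue = thr,
      multiplier = multiplier)
}

#' Merge two abnormal-region masks by pixelwise OR
#'
#' The summative mask applied uniformly to both images of a pair, so both
#' Scores are counted over the same region.
#' @param maskRef,maskAln [RegionMask-class] objects on the same grid (the
#'   aligned-image mask already warped to the reference frame).
#' @return the merged [RegionMask-class]; validity is the AND of the inputs'
#'   validity.
#' @export
mergeMasks <- function(maskRef, maskAln) {
  stopifnot(is(maskRef, "RegionMask"), is(maskAln, "RegionMask"))
  if (!identical(dim(pixels(maskRef)), dim(pixels(maskAln))))
    stop("mask shapes differ")
  RegionMask(pixels(maskRef) == 1 | pixels(maskAln) == 1,
             source = maskRef@source,
             valid = validPixels(maskRef) & validPixels(maskAln))
}

#' Growth rate from two Scores
#'
#' `(testScore - referenceScore) / referenceScore`; undefined (`NA`) when
#' the reference score is zero - never infinity.
#' @param referenceScore,testScore hyperfluorescent pixel counts.
#' @return numeric growth rate, full precision.
#' @examples
#' scoreGrowthRate(26984, 24026)   # -0.1096..., printed as -0.11 at 2 d.p.
#' @export
scoreGrowthRate <- function(referenceScore, testScore) {
  if (referenceScore <= 0) return(NA_real_)
  (testScore - referenceScore) / referenceScore
}

#' Count hyperfluorescent pixels inside a mask
#' @param binarized a [BinarizedImage-class].
#' @param mask a [RegionMask-class] on the same grid.
#' @param valid optional extra logical matrix ANDed in.
#' @return integer pixel count.
#' @export
scoreImage <- function(binarized, mask, valid = NULL) {
  stopifnot(is(binarized, "BinarizedImage"), is(mask, "RegionMask"))
  sel <- pixels(binarized) == 1 & pixels(mask) == 1 & validPixels(binarized)
  if (!is.null(valid)) sel <- sel & valid
  sum(sel)
}

#' Score a single FA image inside a mask (no pair alignment)
#'
#' Flatten, binarize at `multiplier` x mode, count inside the mask. Used for
#' single-frame scoring and as the pipeline half of the ground-truth oracle
#' comparison on synthetic scenes.
#' @param image an [FAImage-class].
#' @param mask a [RegionMask-class].
#' @param config an [faConfig()] list (sigma, multiplier, modeWithinMask).
#' @return list with `score`, `binarized`, `corrected`.
#' @export
scoreSingle <- function(image, mask, config = faConfig()) {
  corr <- flattenBackground(image, sigma = config$sigma)
  bin <- binarizeImage(corr, multiplier = config$multiplier,
                       modeWithin = if (config$modeWithinMask) mask else NULL)
  list(score = scoreImage(bin, mask), binarized = bin, corrected = corr)
}

#' Score an FA image pair: full alignment-to-Growth-rate pipeline
#'
#' Registers the test (Aligned) image onto the reference, warps its image
#' and mask, flattens both with Gaussian background division, histogram-
#' matches the test to the reference, binarizes both at `multiplier` x mode,
#' merges the masks (OR) and counts hyperfluorescent pixels inside the
#' merged mask over mutually valid pixels. Pixels invalidated by warping are
#' excluded from modes and both Scores symmetrically, so frame edges cannot
#' bias the Growth rate.
#'
#' @param reference,test [FAImage-class] objects (reference fixed, test is
#'   moved).
#' @param maskRef,maskTest [RegionMask-class] objects in each image's own
#'   frame (the test mask is warped with the estimated transform).
#' @param config an [faConfig()] list.
#' @param transform optional known [AffineParams-class] (skips estimation).
#' @param correspondences optional [CorrespondenceSet-class] (e.g. from a
#'   CSV fallback) used instead of automatic detection.
#' @return a [ScoreReport-class]; `details` carries modes, thresholds, the
#'   transform and intermediate objects when `config$keepIntermediates`.
#' @export
scorePair <- function(reference, test, maskRef, maskTest,
                      config = faConfig(), transform = NULL,
                      correspondences = NULL) {
  stopifnot(is(reference, "FAImage"), is(test, "FAImage"),
            is(maskRef, "RegionMask"), is(maskTest, "RegionMask"))
  if (is.null(transform)) {
    corr <- correspondences
    if (is.null(corr))
      corr <- detectCorrespondences(reference, test,
                                    threshold = config$fastThreshold,
                                    maxKeypoints = config$maxKeypoints)
    transform <- tryCatch(
      estimateAffine(corr, residualThreshold = config$residualThreshold,
                     maxIter = config$ransacMaxIter, seed = config$seed),
      error = function(e) stop(
        "registration failed (", conditionMessage(e), ")",
        call. = FALSE))
  }

  testW <- applyAffine(test, transform)
  maskTestW <- applyAffine(maskTest, transform)
  validCommon <- validPixels(reference) & validPixels(testW)

  corrRef <- flattenBackground(reference, sigma = config$sigma,
                               valid = validCommon)
  corrTest <- flattenBackground(testW, sigma = config$sigma,
                                valid = validCommon)
  if (isTRUE(config$matchHistograms)) {
    if (config$matchDirection == "test_to_reference") {
      corrTest <- matchHistogram(corrTest, corrRef)
    } else {
      corrRef <- matchHistogram(corrRef, corrTest)
    }
  }

  merged <- mergeMasks(maskRef, maskTestW)
  modeWithin <- if (config$modeWithinMask) merged else NULL
  binRef <- binarizeImage(corrRef, multiplier = config$multiplier,
                          valid = validCommon, modeWithin = modeWithin)
  binTest <- binarizeImage(corrTest, multiplier = config$multiplier,
                           valid = validCommon, modeWithin = modeWithin)

  refScore <- scoreImage(binRef, merged, validCommon)
  tstScore <- scoreImage(binTest, merged, validCommon)
  mergedArea <- sum(pixels(merged) == 1 & validCommon)

  details <- list(
    transform = transform,
    modeReference = binRef@modeValue, modeTest = binTest@modeValue,
    thresholdReference = binRef@thresholdValue,
    thresholdTest = binTest@thresholdValue,
    validPixelCount = sum(validCommon),
    testMaskArea = sum(pixels(maskTestW) == 1 & validCommon),
    referenceMaskArea = sum(pixels(maskRef) == 1 & validCommon))
  if (isTRUE(config$keepIntermediates))
    details$intermediates <- list(correctedReference = corrRef,
                                  correctedTest = corrTest,
                                  binarizedReference = binRef,
                                  binarizedTest = binTest,
                                  mergedMask = merged,
                                  warpedTest = testW)

  new("ScoreReport", referenceScore = refScore, testScore = tstScore,
      mergedMaskArea = mergedArea,
      growthRate = scoreGrowthRate(refScore, tstScore),
      maskSources = c(maskRef@source, maskTest@source),
      details = details)
}

#' Emit a ScoreReport as JSON and/or a one-line CSV
#'
#' @param report a [ScoreReport-class].
#' @param jsonPath,csvPath output paths (either may be `NULL`).
#' @param referencePath,testPath provenance strings recorded in the CSV.
#' @param extra named list merged into the JSON (e.g. config, seeds).
#' @return invisibly, the list written to JSON.
#' @export
writeScoreReport <- function(report, jsonPath = NULL, csvPath = NULL,
                             referencePath = "", testPath = "",
                             extra = list()) {
  out <- c(list(reference_score = report@referenceScore,
                test_score = report@testScore,
                merged_mask_area = report@mergedMaskArea,
                growth_rate = report@growthRate,
                mask_sources = report@maskSources),
           extra)
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(csvPath)) {
    d <- data.frame(reference_path = referencePath, test_path = testPath,
                    reference_score = report@referenceScore,
                    test_score = report@testScore,
                    merged_mask_area = report@mergedMaskArea,
                    growth_rate = report@growthRate)
    utils::write.csv(d, csvPath, row.names = FALSE)
  }
  invisible(out)
}

#' Write a review overlay PNG: mask outline plus hyperfluorescent pixels
#'
#' Grayscale base image with the merged-mask boundary and the binarized
#' hyperfluorescent pixels highlighted in distinct channels, for manual
#' review of a scored pair.
#' @param image an [FAImage-class] (the frame to annotate).
#' @param binarized a [BinarizedImage-class].
#' @param mask the merged [RegionMask-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeOverlay <- function(image, binarized, mask, path) {
  g <- pixels(image) / 255
  m <- pixels(mask)
  ## mask outline: mask pixels with at least one non-mask 4-neighbour
  H <- nrow(m); W <- ncol(m)
  nb <- matrix(0, H, W)
  nb[-1, ] <- nb[-1, ] + m[-H, ]; nb[-H, ] <- nb[-H, ] + m[-1, ]
  nb[, -1] <- nb[, -1] + m[, -W]; nb[, -W] <- nb[, -W] + m[, -1]
  outline <- m == 1 & nb < 4
  hyper <- pixels(binarized) == 1 & m == 1
  rgb <- array(g, dim = c(H, W, 3))
  rgb[, , 2][hyper] <- 1; rgb[, , 1][hyper] <- 0.2; rgb[, , 3][hyper] <- 0.2
  rgb[, , 1][outline] <- 1; rgb[, , 2][outline] <- 1; rgb[, , 3][outline] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
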