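## End-to-end orchestration: configuration, single-pair runs, and
## time-series runs against a fixed baseline, with reproducible provenance.

#' Pipeline run configuration
#'
#' Houses the method's fixed constants (sigma = 70 px background blur,
#' 1.2x-mode binarization threshold, 496 px frames) and every tunable knob;
#' serializes losslessly to/from JSON.
#'
#' @param sigma Gaussian background sigma in pixels (70).
#' @param multiplier binarization threshold multiplier (1.2).
#' @param probThreshold segmenter probability cutoff (0.5).
#' @param residualThreshold RANSAC inlier threshold in pixels (3).
#' @param ransacMaxIter RANSAC iteration cap (2000).
#' @param fastThreshold FAST corner threshold (20).
#' @param maxKeypoints keypoints per frame (500).
#' @param seed RNG seed for RANSAC (and anything stochastic downstream).
#' @param maskSource "model", "annotation_file" or "synthetic_truth".
#' @param modeWithinMask compute the binarization mode inside the merged
#'   mask only (default FALSE: whole valid image).
#' @param matchHistograms apply histogram matching to the pair (default
#'   TRUE). Exact histogram specification equalizes the two global intensity
#'   distributions, which also attenuates genuine in-mask growth; disable it
#'   for photometrically calibrated pairs.
#' @param matchDirection "test_to_reference" (default) or
#'   "reference_to_test" histogram matching.
#' @param keepIntermediates retain intermediate images in the ScoreReport.
#' @param writeIntermediates write intermediate PNGs when an output
#'   directory is given.
#' @return a named list of class `fa_config`.
#' @export
faConfig <- function(sigma = 70, multiplier = 1.2, probThreshold = 0.5,
                     residualThreshold = 3, ransacMaxIter = 2000,
                     fastThreshold = 20, maxKeypoints = 500, seed = 1,
                     maskSource = c("annotation_file", "model",
                                    "synthetic_truth"),
                     modeWithinMask = FALSE, matchHistograms = TRUE,
                     matchDirection = c("test_to_reference",
                                        "reference_to_test"),
                     keepIntermediates = FALSE, writeIntermediates = TRUE) {
  structure(list(sigma = as.numeric(sigma),
                 multiplier = as.numeric(multiplier),
                 probThreshold = as.numeric(probThreshold),
                 residualThreshold = as.numeric(residualThreshold),
                 ransacMaxIter = as.integer(ransacMaxIter),
                 fastThreshold = as.numeric(fastThreshold),
                 maxKeypoints = as.integer(maxKeypoints),
                 seed = as.integer(seed),
                 maskSource = match.arg(maskSource),
                 modeWithinMask = modeWithinMask,
                 matchHistograms = matchHistograms,
                 matchDirection = match.arg(matchDirection),
                 keepIntermediates = keepIntermediates,
                 writeIntermediates = writeIntermediates),
            class = "fa_config")
}

#' Serialize / restore a run configuration
#' @param config an [faConfig()] list.
#' @param path JSON file path.
#' @return `readFaConfig` returns the restored `fa_config`.
#' @export
writeFaConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFaConfig
#' @export
readFaConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(faConfig, x)
}

.resolveMask <- function(image, config, model = NULL, maskPath = NULL) {
  switch(config$maskSource,
    model = {
      if (is.null(model)) stop("maskSource='model' but no model given")
      predictMask(model, image, config$probThreshold)
    },
    annotation_file = {
      if (is.null(maskPath))
        stop("maskSource='annotation_file' but no mask path given")
      readRegionMask(maskPath, size = nrow(pixels(image)))
    },
    synthetic_truth = {
      sc <- image@metadata$scene
      if (is.null(sc)) stop("maskSource='synthetic_truth' needs a synthetic image")
      sceneTruthMask(sc)
    })
}

.writeRunArtifacts <- function(report, outputDir, tag, reference, config) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(outputDir, paste0(tag, "_report.json"))
  csvPath <- file.path(outputDir, paste0(tag, "_report.csv"))
  cfg <- unclass(config)
  writeScoreReport(report, jsonPath, csvPath,
                   extra = list(config = cfg,
                                config_hash = provenanceHash(
                                  jsonlite::toJSON(cfg, auto_unbox = TRUE)),
                                seed = config$seed))
  if (isTRUE(config$writeIntermediates) &&
      !is.null(report@details$intermediates)) {
    it <- report@details$intermediates
    writeFAImage(it$warpedTest, file.path(outputDir, paste0(tag, "_aligned.png")))
    writeRegionMask(it$mergedMask, file.path(outputDir, paste0(tag, "_merged_mask.png")))
    writeRegionMask(RegionMask(pixels(it$binarizedReference)),
                    file.path(outputDir, paste0(tag, "_binarized_ref.png")))
    writeRegionMask(RegionMask(pixels(it$binarizedTest)),
                    file.path(outputDir, paste0(tag, "_binarized_test.png")))
    writeOverlay(reference, it$binarizedReference, it$mergedMask,
                 file.path(outputDir, paste0(tag, "_overlay_ref.png")))
    writeOverlay(it$warpedTest, it$binarizedTest, it$mergedMask,
                 file.path(outputDir, paste0(tag, "_overlay_test.png")))
    writeAffine(report@details$transform,
                csvPath = file.path(outputDir, paste0(tag, "_transform.csv")),
                jsonPath = file.path(outputDir, paste0(tag, "_transform.json")))
  }
  invisible(jsonPath)
}

#' Run the full pipeline on one FA image pair
#'
#' Reads and preprocesses both images, resolves the abnormal-region masks
#' (trained model, annotation files, or synthetic truth), registers, and
#' scores. When `outputDir` is given, all intermediates plus the JSON/CSV
#' report (embedding the config and seed) are written there.
#'
#' @param referencePath,testPath image file paths (PNG/TIFF), or
#'   [FAImage-class] objects.
#' @param config an [faConfig()] list.
#' @param model optional [SegmenterModel-class] (for maskSource "model").
#' @param referenceMaskPath,testMaskPath annotation mask paths (for
#'   maskSource "annotation_file").
#' @param correspondencesPath optional CSV of manual correspondences used
#'   when automatic detection fails or is overridden.
#' @param transform optional known [AffineParams-class] (e.g. identity for
#'   device-registered exports); skips keypoint registration.
#' @param outputDir optional artifact directory.
#' @param tag filename stem for artifacts (default "pair").
#' @return a [ScoreReport-class].
#' @export
runPair <- function(referencePath, testPath, config = faConfig(),
                    model = NULL, referenceMaskPath = NULL,
                    testMaskPath = NULL, correspondencesPath = NULL,
                    transform = NULL, outputDir = NULL, tag = "pair") {
  ref <- if (is(referencePath, "FAImage")) referencePath
         else readFAImage(referencePath)
  tst <- if (is(testPath, "FAImage")) testPath else readFAImage(testPath)
  maskRef <- .resolveMask(ref, config, model, referenceMaskPath)
  maskTest <- .resolveMask(tst, config, model, testMaskPath)
  corr <- if (!is.null(correspondencesPath))
    readCorrespondences(correspondencesPath) else NULL
  if (!is.null(outputDir)) config$keepIntermediates <- TRUE
  report <- scorePair(ref, tst, maskRef, maskTest, config,
                      transform = transform, correspondences = corr)
  if (!is.null(outputDir))
    .writeRunArtifacts(report, outputDir, tag, ref, config)
  report
}

#' Run the pipeline over a dated image series against the first visit
#'
#' Every later image is paired with the first (baseline) image, giving the
#' per-visit Growth rate and mask-area trajectory. A discrepancy flag marks
#' visits where the mask area grows while the Growth rate falls - the
#' signature of newly blocked fluorescence (e.g. haemorrhage) inside an
#' enlarging lesion. One failed pair is recorded as NA and does not abort
#' the series; a 2-image series equals pair mode exactly.
#'
#' @param paths image file paths (or [FAImage-class] objects) ordered by
#'   date; the first is the baseline.
#' @param config an [faConfig()] list; `baseline = "previous"` compares each
#'   visit to its predecessor instead.
#' @param maskPaths optional list of annotation mask paths matching `paths`.
#' @param model optional [SegmenterModel-class].
#' @param baseline "first" (default) or "previous".
#' @param assumeAligned treat the series as already registered (identity
#'   transform for every pair), as with device-registered exports.
#' @param outputDir optional artifact directory.
#' @return list with `reports` (per-visit [ScoreReport-class] or `NULL`) and
#'   `trajectory` (data.frame: visit, growth_rate, mask_area,
#'   discrepancy).
#' @export
runSeries <- function(paths, config = faConfig(), maskPaths = NULL,
                      model = NULL, baseline = c("first", "previous"),
                      assumeAligned = FALSE, outputDir = NULL) {
  baseline <- match.arg(baseline)
  if (length(paths) < 2) stop("a series needs at least 2 images")
  n <- length(paths)
  reports <- vector("list", n - 1)
  growth <- maskArea <- rep(NA_real_, n - 1)
  for (i in 2:n) {
    bi <- if (baseline == "first") 1L else i - 1L
    reports[[i - 1]] <- tryCatch(
      runPair(paths[[bi]], paths[[i]], config, model = model,
              referenceMaskPath = if (!is.null(maskPaths)) maskPaths[[bi]],
              testMaskPath = if (!is.null(maskPaths)) maskPaths[[i]],
              transform = if (assumeAligned) affineIdentity(),
              outputDir = outputDir, tag = sprintf("visit%02d", i)),
      error = function(e) {
        warning("visit ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(reports[[i - 1]])) {
      growth[i - 1] <- reports[[i - 1]]@growthRate
      maskArea[i - 1] <- reports[[i - 1]]@details$testMaskArea
    }
  }
  dG <- c(NA, diff(growth)); dM <- c(NA, diff(maskArea))
  traj <- data.frame(visit = 2:n, growth_rate = growth, mask_area = maskArea,
                     discrepancy = !is.na(dG) & !is.na(dM) & dM > 0 & dG < 0)
  list(reports = reports, trajectory = traj)
}
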