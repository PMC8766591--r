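## Synthetic fundus scenes with exact ground truth.
##
## A scene decomposes an early-phase FA-like frame into layers that mimic the
## features that make real FA pairs hard to compare: a dark background, a
## branching bright vessel tree (whose bifurcations give corner features for
## registration), one or two lesion blobs carrying speckled ("mottled")
## hyperfluorescence with unclear boundaries, and a smooth multiplicative
## luminance slope. Every layer is retained, so each pipeline stage can be
## validated against exact truth.

## stamp a disc of given integer radius at (r, c) onto a logical canvas
.discOffsets <- function(radius) {
  key <- sprintf("disc_%d", radius)
  if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 0.25, ]
  .pkgCache[[key]] <- as.matrix(g)
  .pkgCache[[key]]
}

.drawVesselTree <- function(width, height, nTrunks, scale) {
  canvas <- matrix(FALSE, height, width)
  stamp <- function(r, c, w) {
    off <- .discOffsets(max(0L, as.integer(round(w))))
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= height & cc >= 1 & cc <= width
    canvas[cbind(rr[ok], cc[ok])] <<- TRUE
  }
  ## branches queued as (x, y, angle, width, generation)
  x0 <- 0.06 * width
  queue <- lapply(seq_len(nTrunks), function(i) {
    list(x = x0, y = stats::runif(1, 0.25, 0.75) * height,
         angle = stats::runif(1, -0.9, 0.9), w = 3 * scale, gen = 1L)
  })
  step <- max(1.5, 2 * scale)
  segs <- 0L
  while (length(queue) && segs < 64L) {
    b <- queue[[1]]; queue <- queue[-1]
    segs <- segs + 1L
    nSteps <- as.integer(stats::runif(1, 0.25, 0.7) * width / step)
    for (s in seq_len(nSteps)) {
      b$x <- b$x + step * cos(b$angle)
      b$y <- b$y + step * sin(b$angle)
      if (b$x < 2 || b$x > width - 1 || b$y < 2 || b$y > height - 1) break
      stamp(round(b$y), round(b$x), b$w)
      b$angle <- b$angle + stats::rnorm(1, 0, 0.08)
      if (b$gen < 4L && b$w >= 1 && stats::runif(1) < 0.035) {
        d <- stats::runif(1, 0.35, 0.8)
        wid <- b$w * stats::runif(2, 0.6, 0.85)
        queue <- c(queue, list(
          list(x = b$x, y = b$y, angle = b$angle + d, w = wid[1], gen = b$gen + 1L),
          list(x = b$x, y = b$y, angle = b$angle - d, w = wid[2], gen = b$gen + 1L)))
        b$w <- b$w * 0.85
        break
      }
    }
    ## continue the parent after a bifurcation
    if (b$gen < 5L && b$w >= 0.9 &&
        b$x > 2 && b$x < width - 1 && b$y > 2 && b$y < height - 1 && segs < 64L)
      queue <- c(queue, list(b))
  }
  canvas
}

.drawLesions <- function(width, height, nLesions, radiusRange) {
  lesion <- matrix(FALSE, height, width)
  cx <- col(lesion) - 1; cy <- row(lesion) - 1
  for (i in seq_len(nLesions)) {
    r0 <- stats::runif(1, radiusRange[1], radiusRange[2])
    x0 <- stats::runif(1, 0.32, 0.68) * width
    y0 <- stats::runif(1, 0.32, 0.68) * height
    ## irregular boundary: radius modulated by low-order harmonics
    k <- 2:5
    a <- stats::rnorm(length(k), 0, 0.07)
    ph <- stats::runif(length(k), 0, 2 * pi)
    th <- atan2(cy - y0, cx - x0)
    mod <- matrix(1, height, width)
    for (j in seq_along(k)) mod <- mod + a[j] * cos(k[j] * th + ph[j])
    d2 <- (cx - x0)^2 + (cy - y0)^2
    lesion <- lesion | (d2 <= (r0 * pmax(mod, 0.5))^2)
  }
  lesion
}

.drawIllumination <- function(width, height, amplitude) {
  nx <- (col(matrix(0, height, width)) - 1) / (width - 1) - 0.5
  ny <- (row(matrix(0, height, width)) - 1) / (height - 1) - 0.5
  ax <- stats::runif(1, -amplitude, amplitude)
  ay <- stats::runif(1, -amplitude, amplitude)
  bump <- stats::runif(1, -0.15, 0.15)
  bx <- stats::runif(1, -0.25, 0.25); by <- stats::runif(1, -0.25, 0.25)
  f <- 1 + ax * nx + ay * ny + bump * exp(-((nx - bx)^2 + (ny - by)^2) / (2 * 0.35^2))
  clipRange(f, 0.7, 1.3)
}

#' Generate a synthetic FA scene with full ground truth
#'
#' Draws a branching vessel tree, one or two irregular lesion blobs, a
#' band-pass speckle ("mottle") texture confined to the lesion, and a smooth
#' multiplicative illumination slope. Reproducible: the scene is a pure
#' function of its parameters and `seed`.
#'
#' @param width,height grid size in pixels (default the canonical 496).
#' @param seed integer RNG seed.
#' @param nLesions number of lesion blobs; `NULL` draws 1 or 2.
#' @param lesionRadiusFrac lesion radius range as a fraction of the smaller
#'   image side (default 0.12-0.22, i.e. 60-110 px at 496).
#' @param mottleFraction fraction of lesion pixels carrying speckle (0.3).
#' @param nVesselTrunks number of primary vessel trunks (3).
#' @param baseIntensity background 8-bit level (90).
#' @param lesionGain diffuse elevation of the lesion interior (10): window
#'   defects show mildly raised background fluorescence under the speckle.
#' @param vesselGain,mottleGain additive gains of vessels and speckle (70),
#'   placing both well above the 1.2x-mode threshold after flattening.
#' @param illuminationAmplitude maximum relative slope of the luminance
#'   field (0.25, capped at +/-30%).
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- syntheticScene(width = 128, height = 128, seed = 1)
#' img <- renderScene(sc)
#' @export
syntheticScene <- function(width = FA_SIZE, height = FA_SIZE, seed = 1,
                           nLesions = NULL, lesionRadiusFrac = c(0.12, 0.22),
                           mottleFraction = 0.3, nVesselTrunks = 3,
                           baseIntensity = 90, lesionGain = 10,
                           vesselGain = 70, mottleGain = 70,
                           illuminationAmplitude = 0.25) {
  stopifnot(width >= 32, height >= 32, illuminationAmplitude <= 0.3)
  width <- as.integer(width); height <- as.integer(height)
  withSeed(seed, {
    if (is.null(nLesions)) nLesions <- sample(1:2, 1)
    scale <- min(width, height) / FA_SIZE
    vessel <- .drawVesselTree(width, height, nVesselTrunks, max(scale, 0.5))
    lesion <- .drawLesions(width, height, nLesions,
                           lesionRadiusFrac * min(width, height))
    ## band-pass speckle at sigma 2/4.5 px: mottle patches are multi-pixel
    ## structures (as in real FA), not single-pixel noise
    noise <- matrix(stats::rnorm(width * height), height, width)
    band <- gaussianBlurReflect(noise, 2) - gaussianBlurReflect(noise, 4.5)
    mottle <- matrix(FALSE, height, width)
    if (any(lesion) && mottleFraction > 0) {
      thr <- stats::quantile(band[lesion], 1 - mottleFraction)
      mottle <- lesion & band > thr
    }
    illum <- .drawIllumination(width, height, illuminationAmplitude)
    new("SyntheticScene", width = width, height = height,
        vesselMap = matrix(as.numeric(vessel), height, width),
        lesionMask = matrix(as.numeric(lesion), height, width),
        mottleMap = matrix(as.numeric(mottle), height, width),
        illumination = illum, baseIntensity = baseIntensity,
        lesionGain = lesionGain, vesselGain = vesselGain,
        mottleGain = mottleGain, seed = as.integer(seed))
  })
}

#' Construct a SyntheticScene from explicit layers
#'
#' Low-level constructor for tests and degenerate cases (empty vessels, flat
#' illumination); layers must satisfy the class invariants.
#' @param vesselMap,lesionMask,mottleMap 0/1 matrices of a common shape.
#' @param illumination positive matrix, same shape (default flat 1).
#' @param baseIntensity,lesionGain,vesselGain,mottleGain render levels.
#' @param seed integer tag recording provenance.
#' @return a [SyntheticScene-class].
#' @export
SyntheticScene <- function(vesselMap, lesionMask, mottleMap,
                           illumination = NULL, baseIntensity = 90,
                           lesionGain = 10, vesselGain = 70, mottleGain = 70,
                           seed = 0L) {
  d <- dim(lesionMask)
  for (m in list(vesselMap, mottleMap))
    if (!identical(dim(m), d))
      stop("scene layer dimensions disagree with the lesion mask")
  if (is.null(illumination)) illumination <- matrix(1, d[1], d[2])
  new("SyntheticScene", width = as.integer(d[2]), height = as.integer(d[1]),
      vesselMap = matrix(as.numeric(vesselMap != 0), d[1], d[2]),
      lesionMask = matrix(as.numeric(lesionMask != 0), d[1], d[2]),
      mottleMap = matrix(as.numeric(mottleMap != 0), d[1], d[2]),
      illumination = illumination, baseIntensity = baseIntensity,
      lesionGain = lesionGain, vesselGain = vesselGain,
      mottleGain = mottleGain, seed = as.integer(seed))
}

#' Render a synthetic scene to an 8-bit FA image
#'
#' Composes `clip(base + lesionGain*lesion + vesselGain*vessel +
#' mottleGain*mottle)` multiplied by the illumination field, quantized to
#' 8 bits. Deterministic: rendering uses no RNG, all stochastic structure is
#' baked into the scene layers.
#'
#' @param scene a [SyntheticScene-class].
#' @return an [FAImage-class] with the scene attached as
#'   `metadata(scene)$scene` ground truth.
#' @export
renderScene <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  validObject(scene)
  raw <- scene@baseIntensity +
    scene@lesionGain * scene@lesionMask +
    scene@vesselGain * scene@vesselMap +
    scene@mottleGain * scene@mottleMap
  raw <- clipRange(raw, 0, 255)
  img <- clipRange(round(raw * scene@illumination), 0, 255)
  FAImage(img, source = "synthetic", metadata = list(scene = scene))
}

#' Ground-truth abnormal-region mask of a scene
#' @param scene a [SyntheticScene-class].
#' @return a [RegionMask-class] with `source = "synthetic_truth"`.
#' @export
sceneTruthMask <- function(scene) {
  RegionMask(scene@lesionMask, source = "synthetic_truth")
}

#' Ideal (illumination-free) rendered intensities of a scene
#'
#' The rendered image divided by the true illumination field: the reference
#' an ideal background-flattening step would recover, used as the
#' brute-force scoring oracle.
#' @param scene a [SyntheticScene-class].
#' @return numeric matrix (raw 8-bit-scale units, un-quantized division).
#' @export
sceneIdealIntensities <- function(scene) {
  pixels(renderScene(scene)) / scene@illumination
}

#' Render an aligned/reference FA pair with known transform and shift
#'
#' The reference image is the plain render. The aligned image is rendered
#' afresh from the scene's ground-truth layers resampled into the aligned
#' frame - a second capture of the same anatomy is a sharp image, not an
#' interpolated copy of the first - with an optional brightness/contrast
#' shift `gain * I + offset`. `params` maps aligned coordinates to reference
#' coordinates, so registration should recover exactly `params`.
#'
#' @param scene a [SyntheticScene-class].
#' @param params an [AffineParams-class]; `NULL` for identity.
#' @param gain,offset photometric shift applied to the aligned image.
#' @param noiseSd Gaussian sensor-noise standard deviation (8-bit levels)
#'   added to the aligned capture; 0 (default) for none. Serial captures of
#'   the same eye differ by read noise, so stability studies should use a
#'   few levels here.
#' @param noiseSeed seed for the sensor noise (ignored when `noiseSd = 0`).
#' @return list with elements `reference`, `aligned` ([FAImage-class]) and
#'   `truth` (the [AffineParams-class] used).
#' @details Binary layers are resampled nearest-neighbour (sharp speckle);
#'   the illumination field is sampled bilinearly with edge extension.
#'   Fails if fewer than 80% of lesion pixels survive the transform
#'   in-frame, or if the photometric shift saturates more than 1% of pixels
#'   (histogram matching cannot undo saturation).
#' @export
makePair <- function(scene, params = NULL, gain = 1, offset = 0,
                     noiseSd = 0, noiseSeed = 1) {
  stopifnot(is(scene, "SyntheticScene"))
  ref <- renderScene(scene)
  if (is.null(params)) params <- affineIdentity()
  stopifnot(is(params, "AffineParams"))
  H <- scene@height; W <- scene@width

  les <- which(scene@lesionMask == 1)
  if (length(les)) {
    xy <- cbind(x = (ceiling(les / H)) - 1, y = ((les - 1) %% H))
    back <- affineApplyPoints(affineInvert(params), xy)
    keep <- back[, 1] >= 0 & back[, 1] <= W - 1 &
            back[, 2] >= 0 & back[, 2] <= H - 1
    if (mean(keep) < 0.8)
      stop("transform ejects more than 20% of the lesion from the frame")
  }

  identityT <- isTRUE(all.equal(params@matrix,
                                matrix(c(1, 0, 0, 1, 0, 0), 2, 3)))
  if (identityT && gain == 1 && offset == 0 && noiseSd == 0)
    return(list(reference = ref, aligned = ref, truth = params))

  g <- .mappedGrid(H, W, params)
  layer <- function(m) matrix(.sampleNearest(m, g$xs, g$ys)$values, H, W)
  illumA <- matrix(.sampleBilinear(scene@illumination,
                                   clipRange(g$xs, 0, W - 1),
                                   clipRange(g$ys, 0, H - 1))$values, H, W)
  rawA <- clipRange(scene@baseIntensity +
                      scene@lesionGain * layer(scene@lesionMask) +
                      scene@vesselGain * layer(scene@vesselMap) +
                      scene@mottleGain * layer(scene@mottleMap), 0, 255)
  captured <- rawA * illumA
  if (noiseSd > 0)
    captured <- captured + withSeed(noiseSeed,
      matrix(stats::rnorm(H * W, sd = noiseSd), H, W))
  shifted <- gain * captured + offset
  newlySat <- (shifted < 0 | shifted > 255) & captured > 0 & captured < 255
  if (mean(newlySat) > 0.01)
    stop("photometric shift saturates more than 1% of pixels")
  aligned <- FAImage(clipRange(round(shifted), 0, 255), source = "synthetic",
                     metadata = list(scene = scene, truthTransform = params,
                                     gain = gain, offset = offset))
  list(reference = ref, aligned = aligned, truth = params)
}

#' Draw a random affine transform within clinically mild ranges
#'
#' @param width,height frame size (defines the rotation/scale centre).
#' @param seed integer seed.
#' @param maxTranslation max |tx|, |ty| in pixels (30).
#' @param maxRotation max |rotation| in degrees (10).
#' @param scaleRange isotropic scale range (0.9-1.1).
#' @param maxSkew max shear coefficient (0.02).
#' @return an [AffineParams-class].
#' @export
randomAffine <- function(width = FA_SIZE, height = FA_SIZE, seed = 1,
                         maxTranslation = 30, maxRotation = 10,
                         scaleRange = c(0.9, 1.1), maxSkew = 0.02) {
  withSeed(seed, {
    affineFromComponents(
      translation = stats::runif(2, -maxTranslation, maxTranslation),
      rotation = stats::runif(1, -maxRotation, maxRotation),
      scale = stats::runif(1, scaleRange[1], scaleRange[2]),
      skew = stats::runif(1, -maxSkew, maxSkew),
      center = c((width - 1) / 2, (height - 1) / 2))
  })
}
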