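## Keypoint-based affine registration: FAST corner detection, BRIEF binary
## descriptors matched by Hamming distance with cross-check, and RANSAC
## affine estimation, followed by resampling onto the reference grid.
## Coordinates are 0-based (x, y) with the origin at the top-left pixel
## centre; the estimated transform maps aligned-image coordinates to
## reference coordinates.

## ---- affine helpers --------------------------------------------------------

#' Identity affine transform
#' @return an [AffineParams-class] equal to the identity.
#' @export
affineIdentity <- function() {
  AffineParams(matrix(c(1, 0, 0, 1, 0, 0), 2, 3))
}

#' Build an affine transform from geometric components
#'
#' The linear part is `scale * rotation * shear` applied about `center`,
#' followed by `translation`: `p' = L (p - c) + c + t`.
#' @param translation length-2 (tx, ty) in pixels.
#' @param rotation rotation angle in degrees (counter-clockwise in image
#'   coordinates with y pointing down).
#' @param scale isotropic scale factor.
#' @param skew shear coefficient applied to x as a function of y.
#' @param center length-2 fixed point of the linear part.
#' @return an [AffineParams-class].
#' @export
affineFromComponents <- function(translation = c(0, 0), rotation = 0,
                                 scale = 1, skew = 0, center = c(0, 0)) {
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  K <- matrix(c(1, 0, skew, 1), 2, 2)
  L <- scale * R %*% K
  t0 <- center + translation - L %*% center
  AffineParams(cbind(L, t0))
}

#' Invert an affine transform
#' @param params an [AffineParams-class].
#' @return the inverse [AffineParams-class].
#' @export
affineInvert <- function(params) {
  L <- params@matrix[, 1:2]
  t0 <- params@matrix[, 3]
  Li <- solve(L)
  AffineParams(cbind(Li, -Li %*% t0))
}

#' Apply an affine transform to 0-based (x, y) points
#' @param params an [AffineParams-class].
#' @param xy n x 2 matrix of points.
#' @return n x 2 matrix of transformed points.
#' @export
affineApplyPoints <- function(params, xy) {
  xy <- rbind(xy)  # tolerate a single point given as a vector
  m <- params@matrix
  cbind(m[1, 1] * xy[, 1] + m[1, 2] * xy[, 2] + m[1, 3],
        m[2, 1] * xy[, 1] + m[2, 2] * xy[, 2] + m[2, 3])
}

## ---- resampling ------------------------------------------------------------

## sample mat at continuous 0-based coordinates (xs, ys)
.sampleBilinear <- function(mat, xs, ys) {
  H <- nrow(mat); W <- ncol(mat)
  valid <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
  x0 <- clipRange(floor(xs), 0, W - 2); y0 <- clipRange(floor(ys), 0, H - 2)
  fx <- clipRange(xs - x0, 0, 1); fy <- clipRange(ys - y0, 0, 1)
  i00 <- y0 + 1 + x0 * H
  v <- (1 - fx) * ((1 - fy) * mat[i00] + fy * mat[i00 + 1]) +
       fx * ((1 - fy) * mat[i00 + H] + fy * mat[i00 + H + 1])
  v[!valid] <- 0
  list(values = v, valid = valid)
}

.sampleNearest <- function(mat, xs, ys) {
  H <- nrow(mat); W <- ncol(mat)
  xi <- round(xs); yi <- round(ys)
  valid <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
  xi <- clipRange(xi, 0, W - 1); yi <- clipRange(yi, 0, H - 1)
  v <- mat[yi + 1 + xi * H]
  v[!valid] <- 0
  list(values = v, valid = valid)
}

## grid of 0-based coordinates of every output pixel, mapped through params
.mappedGrid <- function(H, W, params) {
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), W)
  p <- affineApplyPoints(params, cbind(xs, ys))
  list(xs = p[, 1], ys = p[, 2])
}

## forward sampling: out(p) = mat(T(p)); used to synthesize aligned images
warpForwardSample <- function(mat, params, interpolation = "bilinear") {
  g <- .mappedGrid(nrow(mat), ncol(mat), params)
  s <- if (interpolation == "bilinear") .sampleBilinear(mat, g$xs, g$ys)
       else .sampleNearest(mat, g$xs, g$ys)
  list(pixels = matrix(s$values, nrow(mat), ncol(mat)),
       valid = matrix(s$valid, nrow(mat), ncol(mat)))
}

## inverse sampling: out(p) = mat(T^-1(p)); resamples the aligned image onto
## the reference grid
warpMatrix <- function(mat, params, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  warpForwardSample(mat, affineInvert(params), interpolation)
}

#' @describeIn applyAffine FA images: bilinear interpolation, re-quantized to
#'   8 bits; pixels leaving the frame are zero-filled and flagged invalid.
#' @export
setMethod("applyAffine", "FAImage", function(x, params, ...) {
  w <- warpMatrix(pixels(x), params, "bilinear")
  vs <- warpMatrix(matrix(as.numeric(x@valid), nrow(x@valid)), params, "nearest")
  FAImage(clipRange(round(w$pixels), 0, 255), source = x@source,
          valid = w$valid & vs$pixels > 0, metadata = x@metadata)
})

#' @describeIn applyAffine region masks: nearest-neighbour so the result
#'   stays binary.
#' @export
setMethod("applyAffine", "RegionMask", function(x, params, ...) {
  w <- warpMatrix(pixels(x), params, "nearest")
  vs <- warpMatrix(matrix(as.numeric(x@valid), nrow(x@valid)), params, "nearest")
  RegionMask(w$pixels, source = x@source, valid = w$valid & vs$pixels > 0,
             probThreshold = x@probThreshold)
})

## ---- FAST corner detection -------------------------------------------------

## 16-point Bresenham circle of radius 3, clockwise from 12 o'clock
.fastCircle <- cbind(
  dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
  dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))

#' Detect FAST-9 corners
#'
#' Segment-test corners: a pixel is a corner when at least 9 contiguous
#' pixels on the radius-3 circle are all brighter than centre + threshold or
#' all darker than centre - threshold. Vessel bifurcations in FA images are
#' the dominant responders. Non-maximum suppression (3x3) on the sum-of-
#' absolute-differences score; strongest `maxKeypoints` kept.
#'
#' @param image an [FAImage-class] or numeric matrix.
#' @param threshold intensity threshold t (default 20 of 255).
#' @param maxKeypoints cap on the number of corners returned (500).
#' @param margin border (pixels) excluded so descriptors fit (20).
#' @return data.frame with 0-based `x`, `y` and `score`, strongest first.
#' @export
detectKeypoints <- function(image, threshold = 20, maxKeypoints = 500,
                            margin = 20) {
  P <- if (is(image, "FAImage")) pixels(image) else image
  H <- nrow(P); W <- ncol(P)
  if (H < 2 * margin + 8 || W < 2 * margin + 8)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  rows <- (margin + 1):(H - margin)
  cols <- (margin + 1):(W - margin)
  C <- P[rows, cols]
  ## high-speed pretest on the 4 compass points (1, 5, 9, 13)
  compass <- c(1L, 5L, 9L, 13L)
  nb <- nd <- matrix(0L, length(rows), length(cols))
  for (k in compass) {
    V <- P[rows + .fastCircle[k, "dy"], cols + .fastCircle[k, "dx"]]
    nb <- nb + (V > C + threshold)
    nd <- nd + (V < C - threshold)
  }
  cand <- which(nb >= 3L | nd >= 3L)
  if (!length(cand))
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  cr <- rows[(cand - 1L) %% length(rows) + 1L]
  cc <- cols[(cand - 1L) %/% length(rows) + 1L]
  cv <- P[cbind(cr, cc)]
  V16 <- matrix(0, length(cand), 16)
  for (k in 1:16)
    V16[, k] <- P[cbind(cr + .fastCircle[k, "dy"], cc + .fastCircle[k, "dx"])]
  bright <- V16 > cv + threshold
  dark <- V16 < cv - threshold
  runOf9 <- function(B) {
    BB <- cbind(B, B[, 1:8, drop = FALSE])
    hit <- rep(FALSE, nrow(B))
    for (s in 1:16) hit <- hit | (rowSums(BB[, s:(s + 8), drop = FALSE]) == 9L)
    hit
  }
  isCorner <- runOf9(bright) | runOf9(dark)
  if (!any(isCorner))
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  keep <- which(isCorner)
  score <- pmax(rowSums(pmax(V16[keep, , drop = FALSE] - (cv[keep] + threshold), 0)),
                rowSums(pmax((cv[keep] - threshold) - V16[keep, , drop = FALSE], 0)))
  ## 3x3 non-maximum suppression on a sparse score map
  S <- matrix(0, H, W)
  S[cbind(cr[keep], cc[keep])] <- score
  M <- S
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    M[(1 - min(dr, 0)):(H - max(dr, 0)), (1 - min(dc, 0)):(W - max(dc, 0))] <-
      pmax(M[(1 - min(dr, 0)):(H - max(dr, 0)), (1 - min(dc, 0)):(W - max(dc, 0))],
           S[(1 + max(dr, 0)):(H + min(dr, 0)), (1 + max(dc, 0)):(W + min(dc, 0))])
  }
  nms <- S[cbind(cr[keep], cc[keep])] >= M[cbind(cr[keep], cc[keep])]
  kp <- data.frame(x = cc[keep][nms] - 1, y = cr[keep][nms] - 1,
                   score = score[nms])
  kp <- kp[order(-kp$score, kp$y, kp$x), , drop = FALSE]
  utils::head(kp, maxKeypoints)
}

## ---- BRIEF descriptors -----------------------------------------------------

## fixed 256-pair sampling pattern within a 31x31 patch (isotropic Gaussian,
## frozen seed: the pattern is a package constant, not a tuning knob)
.briefPattern <- function() {
  if (!is.null(.pkgCache$brief)) return(.pkgCache$brief)
  .pkgCache$brief <- withSeed(31L, {
    p <- matrix(round(stats::rnorm(256 * 4, sd = 31 / 5)), ncol = 4)
    clipRange(p, -15, 15)
  })
  .pkgCache$brief
}

#' Compute BRIEF-256 descriptors at keypoint locations
#'
#' Binary descriptors: 256 intensity comparisons between fixed point pairs
#' in the Gaussian-smoothed (sigma = 2) patch around each keypoint.
#' @param image an [FAImage-class] or numeric matrix.
#' @param keypoints data.frame with 0-based `x`, `y` (from
#'   [detectKeypoints()]); points closer than 16 px to the border are dropped.
#' @return list with `descriptors` (n x 256 0/1 matrix) and `keypoints`
#'   (the rows actually described).
#' @export
briefDescriptors <- function(image, keypoints) {
  P <- if (is(image, "FAImage")) pixels(image) else image
  H <- nrow(P); W <- ncol(P)
  ok <- keypoints$x >= 16 & keypoints$x <= W - 17 &
        keypoints$y >= 16 & keypoints$y <= H - 17
  keypoints <- keypoints[ok, , drop = FALSE]
  n <- nrow(keypoints)
  pat <- .briefPattern()
  if (n == 0)
    return(list(descriptors = matrix(0, 0, 256), keypoints = keypoints))
  S <- gaussianBlurReflect(P, 2)
  D <- matrix(0, n, 256)
  r <- keypoints$y + 1; c <- keypoints$x + 1
  for (k in 1:256) {
    a <- S[cbind(r + pat[k, 2], c + pat[k, 1])]
    b <- S[cbind(r + pat[k, 4], c + pat[k, 3])]
    D[, k] <- as.numeric(a < b)
  }
  list(descriptors = D, keypoints = keypoints)
}

## ---- matching --------------------------------------------------------------

#' Detect correspondences between a reference and an aligned image
#'
#' FAST keypoints on both frames, BRIEF descriptors, nearest-neighbour
#' matching by Hamming distance with mutual cross-check and a distance cap.
#' Fewer than 3 surviving matches signals the CSV-fallback condition with a
#' classed warning (`fascore_fallback`); the (possibly empty) set is still
#' returned so the caller can substitute manual correspondences.
#'
#' @param reference,aligned [FAImage-class] objects.
#' @param threshold FAST intensity threshold (20).
#' @param maxKeypoints keypoints retained per frame (500).
#' @param maxDistance maximum Hamming distance for a usable match (80/256).
#' @return a [CorrespondenceSet-class] (source "automatic"); may contain
#'   outliers — RANSAC downstream is expected to reject them.
#' @export
detectCorrespondences <- function(reference, aligned, threshold = 20,
                                  maxKeypoints = 500, maxDistance = 80) {
  k1 <- detectKeypoints(reference, threshold, maxKeypoints)
  k2 <- detectKeypoints(aligned, threshold, maxKeypoints)
  d1 <- briefDescriptors(reference, k1)
  d2 <- briefDescriptors(aligned, k2)
  empty <- new("CorrespondenceSet",
               reference = matrix(0, 0, 2), aligned = matrix(0, 0, 2),
               source = "automatic")
  if (nrow(d1$descriptors) == 0 || nrow(d2$descriptors) == 0) {
    warning(warningCondition(
      "fewer than 3 correspondences; supply a correspondence CSV",
      class = "fascore_fallback"))
    return(empty)
  }
  A <- d1$descriptors; B <- d2$descriptors
  ham <- 256 - (A %*% t(B) + (1 - A) %*% t(1 - B))
  b12 <- max.col(-ham, ties.method = "first")
  b21 <- max.col(-t(ham), ties.method = "first")
  i <- seq_len(nrow(A))
  mutual <- b21[b12] == i & ham[cbind(i, b12)] <= maxDistance
  if (sum(mutual) < 3)
    warning(warningCondition(
      "fewer than 3 correspondences; supply a correspondence CSV",
      class = "fascore_fallback"))
  new("CorrespondenceSet",
      reference = as.matrix(d1$keypoints[mutual, c("x", "y")]),
      aligned = as.matrix(d2$keypoints[b12[mutual], c("x", "y")]),
      source = "automatic")
}

#' Replace a fraction of correspondences with gross outliers
#'
#' QC utility for robustness checks: a stated fraction of matched pairs has
#' its aligned-side point replaced by a uniformly random in-frame location.
#' @param corr a [CorrespondenceSet-class].
#' @param fraction fraction of pairs corrupted (e.g. 0.3).
#' @param width,height frame size used for the random replacements.
#' @param seed integer seed.
#' @return the corrupted [CorrespondenceSet-class].
#' @export
injectOutliers <- function(corr, fraction, width = FA_SIZE, height = FA_SIZE,
                           seed = 1) {
  n <- nrow(corr@reference)
  k <- round(fraction * n)
  if (k == 0) return(corr)
  withSeed(seed, {
    idx <- sample.int(n, k)
    aln <- corr@aligned
    aln[idx, 1] <- stats::runif(k, 0, width - 1)
    aln[idx, 2] <- stats::runif(k, 0, height - 1)
    new("CorrespondenceSet", reference = corr@reference, aligned = aln,
        source = corr@source)
  })
}

## ---- least squares + RANSAC ------------------------------------------------

## closed-form least-squares affine: aligned -> reference
.fitAffineLS <- function(refPts, alnPts) {
  A <- cbind(alnPts[, 1], alnPts[, 2], 1)
  AtA <- crossprod(A)
  if (abs(det(AtA)) < 1e-8) return(NULL)  # collinear
  sol <- solve(AtA, crossprod(A, refPts))
  rbind(c(sol[1, 1], sol[2, 1], sol[3, 1]),
        c(sol[1, 2], sol[2, 2], sol[3, 2]))
}

.reprojResiduals <- function(M, refPts, alnPts) {
  px <- M[1, 1] * alnPts[, 1] + M[1, 2] * alnPts[, 2] + M[1, 3]
  py <- M[2, 1] * alnPts[, 1] + M[2, 2] * alnPts[, 2] + M[2, 3]
  sqrt((px - refPts[, 1])^2 + (py - refPts[, 2])^2)
}

#' Estimate an affine transform from correspondences by RANSAC
#'
#' Repeatedly fits an exact affine to random minimal samples of 3 pairs,
#' counts inliers within `residualThreshold`, then refits least squares on
#' the best inlier set. Adaptive early termination; reproducible via `seed`.
#'
#' @param corr a [CorrespondenceSet-class] (>= 3 non-collinear pairs).
#' @param residualThreshold inlier reprojection threshold in pixels (3).
#' @param maxIter maximum RANSAC iterations (2000).
#' @param seed integer seed.
#' @return an [AffineParams-class] carrying `inlierCount`/`nCandidates`.
#' @export
estimateAffine <- function(corr, residualThreshold = 3, maxIter = 2000,
                           seed = 1) {
  refPts <- corr@reference; alnPts <- corr@aligned
  n <- nrow(refPts)
  if (n < 3)
    stop("affine estimation needs at least 3 correspondences; ",
         "supply a correspondence CSV (source 'csv_file') as fallback")
  if (n == 3) {
    M <- .fitAffineLS(refPts, alnPts)
    if (is.null(M)) stop("correspondences are collinear")
    return(AffineParams(M, inlierCount = 3L, nCandidates = 3L))
  }
  withSeed(seed, {
    best <- NULL; bestInl <- logical(n); bestCount <- 0L
    iter <- 0L; needed <- maxIter
    while (iter < min(maxIter, needed)) {
      iter <- iter + 1L
      s <- sample.int(n, 3)
      M <- .fitAffineLS(refPts[s, , drop = FALSE], alnPts[s, , drop = FALSE])
      if (is.null(M)) next
      inl <- .reprojResiduals(M, refPts, alnPts) <= residualThreshold
      if (sum(inl) > bestCount) {
        bestCount <- sum(inl); bestInl <- inl; best <- M
        w <- max(bestCount / n, 1e-3)
        needed <- ceiling(log(1e-3) / log(1 - w^3 + 1e-12))
      }
    }
    if (is.null(best) || bestCount < 3)
      stop("RANSAC found no affine model with >= 3 inliers; ",
           "supply a correspondence CSV (source 'csv_file') as fallback")
    M <- .fitAffineLS(refPts[bestInl, , drop = FALSE],
                      alnPts[bestInl, , drop = FALSE])
    if (is.null(M)) M <- best
    inl <- .reprojResiduals(M, refPts, alnPts) <= residualThreshold
    AffineParams(M, inlierCount = sum(inl), nCandidates = n)
  })
}

#' Mean reprojection discrepancy between two affine transforms
#'
#' Mean Euclidean distance between the two mappings over a uniform grid of
#' probe points covering the central field.
#' @param a,b [AffineParams-class] objects.
#' @param width,height frame size probed.
#' @return mean reprojection error in pixels.
#' @export
affineReprojectionError <- function(a, b, width = FA_SIZE, height = FA_SIZE) {
  g <- expand.grid(x = seq(0.1, 0.9, length.out = 9) * (width - 1),
                   y = seq(0.1, 0.9, length.out = 9) * (height - 1))
  pa <- affineApplyPoints(a, as.matrix(g))
  pb <- affineApplyPoints(b, as.matrix(g))
  mean(sqrt(rowSums((pa - pb)^2)))
}

## ---- CSV interchange -------------------------------------------------------

#' Read manual correspondences from CSV
#'
#' Dialect: header `x_ref,y_ref,x_aln,y_aln`, 0-based pixel coordinates.
#' @param path CSV file path.
#' @return a [CorrespondenceSet-class] with source "csv_file".
#' @export
readCorrespondences <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_ref", "y_ref", "x_aln", "y_aln")
  if (!all(need %in% names(d)))
    stop("correspondence CSV must have columns ", paste(need, collapse = ","))
  new("CorrespondenceSet",
      reference = as.matrix(d[, c("x_ref", "y_ref")]),
      aligned = as.matrix(d[, c("x_aln", "y_aln")]),
      source = "csv_file")
}

#' Write correspondences to CSV (same dialect as [readCorrespondences()])
#' @param corr a [CorrespondenceSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCorrespondences <- function(corr, path) {
  d <- data.frame(x_ref = corr@reference[, 1], y_ref = corr@reference[, 2],
                  x_aln = corr@aligned[, 1], y_aln = corr@aligned[, 2])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an estimated transform as CSV (2x3 row-major) and/or JSON
#' @param params an [AffineParams-class].
#' @param csvPath,jsonPath output paths (either may be `NULL`).
#' @return invisibly, a list of the paths written.
#' @export
writeAffine <- function(params, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.table(params@matrix, csvPath, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(matrix = params@matrix,
                              inlierCount = params@inlierCount,
                              nCandidates = params@nCandidates),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csvPath, json = jsonPath))
}
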