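# Keypoint registration: FAST/BRIEF matching, RANSAC estimation, warping.

test_that("affine helpers compose, invert and apply consistently", {
  tr <- affineFromComponents(translation = c(5, -3), rotation = 4,
                             scale = 1.05, skew = 0.01, center = c(60, 60))
  pts <- cbind(runif(20, 0, 120), runif(20, 0, 120))
  there <- affineApplyPoints(tr, pts)
  back <- affineApplyPoints(affineInvert(tr), there)
  expect_lt(max(abs(back - pts)), 1e-9)
  expect_equal(affineIdentity()@matrix, matrix(c(1, 0, 0, 1, 0, 0), 2, 3))
})

test_that("degenerate linear parts are rejected by the validity bound", {
  expect_error(AffineParams(matrix(c(0.1, 0, 0, 0.1, 0, 0), 2, 3)),
               "determinant")
})

test_that("least-squares recovery from exact correspondences is near-exact", {
  tr <- affineFromComponents(translation = c(12, -9), rotation = 6,
                             scale = 0.95, skew = 0.02, center = c(248, 248))
  set.seed(10)
  aln <- cbind(runif(40, 20, 470), runif(40, 20, 470))
  ref <- affineApplyPoints(tr, aln)
  corr <- new("CorrespondenceSet", reference = ref, aligned = aln,
              source = "csv_file")
  est <- estimateAffine(corr, seed = 1)
  expect_lt(max(abs(est@matrix - tr@matrix)), 1e-6)
})

test_that("identity correspondences give the identity matrix", {
  set.seed(11)
  pts <- cbind(runif(10, 0, 495), runif(10, 0, 495))
  corr <- new("CorrespondenceSet", reference = pts, aligned = pts,
              source = "csv_file")
  est <- estimateAffine(corr, seed = 1)
  expect_lt(max(abs(est@matrix - affineIdentity()@matrix)), 1e-9)
})

test_that("RANSAC rejects 30% gross outliers and is seed-reproducible", {
  tr <- affineFromComponents(translation = c(-20, 15), rotation = -7,
                             scale = 1.08, center = c(248, 248))
  set.seed(12)
  aln <- cbind(runif(60, 20, 470), runif(60, 20, 470))
  ref <- affineApplyPoints(tr, aln)
  corr <- new("CorrespondenceSet", reference = ref, aligned = aln,
              source = "csv_file")
  bad <- injectOutliers(corr, 0.3, seed = 5)
  est1 <- estimateAffine(bad, seed = 7)
  est2 <- estimateAffine(bad, seed = 7)
  expect_identical(est1@matrix, est2@matrix)
  expect_lt(affineReprojectionError(est1, tr), 0.5)
  expect_gte(est1@inlierCount, 42)
})

test_that("collinear or insufficient correspondences fail with the CSV hint", {
  pts <- cbind(1:10, 2 * (1:10))  # collinear
  corr <- new("CorrespondenceSet", reference = pts, aligned = pts + 1,
              source = "csv_file")
  expect_error(estimateAffine(corr, seed = 1))
  few <- new("CorrespondenceSet", reference = pts[1:2, ],
             aligned = pts[1:2, ], source = "csv_file")
  expect_error(estimateAffine(few, seed = 1), "CSV")
})

test_that("an image matched with itself yields zero-displacement pairs", {
  img <- renderScene(smallScene(seed = 6, size = 256))
  corr <- detectCorrespondences(img, img)
  expect_gte(nrow(corr@reference), 3)
  expect_true(all(corr@reference == corr@aligned))
})

test_that("known translation appears as the median match displacement", {
  sc <- smallScene(seed = 7, size = 256)
  tr <- affineFromComponents(translation = c(10, -7))
  pr <- makePair(sc, tr)
  corr <- detectCorrespondences(pr$reference, pr$aligned)
  expect_gte(nrow(corr@reference), 3)
  disp <- corr@reference - corr@aligned
  expect_lt(abs(median(disp[, 1]) - 10), 1)
  expect_lt(abs(median(disp[, 2]) - (-7)), 1)
})

test_that("a featureless image raises the CSV-fallback condition", {
  flat <- FAImage(matrix(100, 256, 256))
  expect_warning(corr <- detectCorrespondences(flat, flat),
                 class = "fascore_fallback")
  expect_equal(nrow(corr@reference), 0)
})

test_that("warping: identity no-op, binary closure, round-trip bound", {
  img <- renderScene(smallScene(seed = 8, size = 128))
  same <- applyAffine(img, affineIdentity())
  expect_identical(pixels(same), pixels(img))

  msk <- sceneTruthMask(smallScene(seed = 8, size = 128))
  tr <- affineFromComponents(translation = c(6, 3), rotation = 5,
                             scale = 1.04, center = c(64, 64))
  wm <- applyAffine(msk, tr)
  expect_true(all(pixels(wm) %in% c(0, 1)))

  smooth <- FAImage(round(outer(seq(0, 200, length.out = 128),
                                seq(0, 55, length.out = 128), "+")))
  there <- applyAffine(smooth, tr)
  back <- applyAffine(there, affineInvert(tr))
  inner <- validPixels(back) & validPixels(there)
  inner[c(1:10, 119:128), ] <- FALSE; inner[, c(1:10, 119:128)] <- FALSE
  expect_lt(mean(abs(pixels(back)[inner] - pixels(smooth)[inner])), 2)
})

test_that("correspondence CSV dialect round-trips", {
  pts <- cbind(c(1.5, 20, 300), c(2, 40, 100))
  corr <- new("CorrespondenceSet", reference = pts, aligned = pts + 2,
              source = "csv_file")
  p <- tempfile(fileext = ".csv")
  writeCorrespondences(corr, p)
  back <- readCorrespondences(p)
  expect_equal(unname(back@reference), unname(pts))
  expect_equal(unname(back@aligned), unname(pts + 2))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
  expect_error(readCorrespondences(bad), "columns")
})

test_that("end-to-end recovery within 1 px on mildly transformed pairs", {
  ok <- 0
  for (s in 1:5) {
    sc <- syntheticScene(seed = 60 + s)
    tr <- randomAffine(seed = 160 + s)
    pr <- makePair(sc, tr, gain = 1.02, offset = 2)
    corr <- detectCorrespondences(pr$reference, pr$aligned)
    est <- estimateAffine(corr, seed = s)
    if (affineReprojectionError(est, tr) <= 1) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
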