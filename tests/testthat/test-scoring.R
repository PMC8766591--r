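# Mode computation, binarization, mask merging, Scores and Growth rate.

.corrected <- function(m, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m), ncol(m))
  new("CorrectedImage", pixels = m, valid = valid, sigma = 70, source = "")
}

test_that("mode: constant, dominant-bin and exact-tie cases", {
  expect_equal(computeMode(.corrected(matrix(1, 10, 10))), 1)

  m <- matrix(1, 10, 10); m[1:10] <- 1.5   # 90% at 1.0, 10% at 1.5
  md <- computeMode(.corrected(m))
  expect_lt(abs(md - 1.0), diff(range(m)) / 256)

  # exact 50/50 tie across the two extreme bins: lower bin centre wins
  m2 <- matrix(rep(c(0, 1), each = 50), 10, 10)
  md2 <- computeMode(.corrected(m2))
  expect_lt(md2, 0.5)
  expect_error(computeMode(.corrected(matrix(1, 2, 2),
                                      valid = matrix(FALSE, 2, 2))),
               "no valid")
})

test_that("binarization: strict threshold, floor multiplier, validity", {
  co <- .corrected(matrix(1, 8, 8))
  b <- binarizeImage(co)             # 1.0 is not > 1.2
  expect_true(all(pixels(b) == 0))
  expect_equal(b@thresholdValue, 1.2 * b@modeValue)

  m <- matrix(runif(64, 0.5, 2), 8, 8)
  b0 <- binarizeImage(.corrected(m), multiplier = 0)
  expect_true(all(pixels(b0)[m > 0] == 1))

  valid <- matrix(TRUE, 8, 8); valid[1:4, ] <- FALSE
  bv <- binarizeImage(.corrected(m, valid), multiplier = 0)
  expect_true(all(pixels(bv)[1:4, ] == 0))
})

test_that("binarized set matches the ground-truth bright set on a scene", {
  sc <- discScene(size = 128, r = 40)
  img <- renderScene(sc)
  b <- binarizeImage(flattenBackground(img, sigma = 20))
  truthSet <- sc@mottleMap == 1 | sc@vesselMap == 1
  disagree <- sum(pixels(b) != as.numeric(truthSet))
  expect_lte(disagree, 0.01 * length(truthSet))
})

test_that("mask merging is a pixelwise OR with inclusion-exclusion area", {
  z <- matrix(0, 20, 20)
  a <- z; a[1:10, 1:10] <- 1          # 100 px
  b <- z; b[15:19, 1:10] <- 1         # 50 px, disjoint
  m <- mergeMasks(RegionMask(a), RegionMask(b))
  expect_equal(sum(pixels(m)), 150)
  expect_identical(pixels(mergeMasks(RegionMask(a), RegionMask(a))), a)

  set.seed(31)
  c1 <- matrix(rbinom(400, 1, 0.3), 20, 20)
  c2 <- matrix(rbinom(400, 1, 0.3), 20, 20)
  got <- sum(pixels(mergeMasks(RegionMask(c1), RegionMask(c2))))
  expect_equal(got, sum(c1) + sum(c2) - sum(c1 == 1 & c2 == 1))
  expect_error(mergeMasks(RegionMask(a), RegionMask(matrix(0, 10, 10))),
               "shapes")
})

test_that("growth rate follows its defining formula and edge cases", {
  g <- scoreGrowthRate(26984, 24026)
  expect_equal(g, (24026 - 26984) / 26984)
  expect_equal(round(g, 2), -0.11)
  expect_identical(scoreGrowthRate(0, 10), NA_real_)
  expect_equal(scoreGrowthRate(100, 100), 0)
})

test_that("an image paired with itself scores growth exactly 0", {
  sc <- smallScene(seed = 33)
  img <- renderScene(sc)
  rep <- scorePair(img, img, sceneTruthMask(sc), sceneTruthMask(sc),
                   truthConfig(), transform = affineIdentity())
  expect_identical(rep@growthRate, 0)
  expect_equal(rep@referenceScore, rep@testScore)
})

test_that("swapping reference and test maps g to 1/(1+g) - 1", {
  sc1 <- discScene(size = 128, r = 40, mottleFraction = 0.25)
  sc2 <- discScene(size = 128, r = 40, mottleFraction = 0.30)
  i1 <- renderScene(sc1); i2 <- renderScene(sc2)
  m1 <- sceneTruthMask(sc1); m2 <- sceneTruthMask(sc2)
  # identical photometric conditions: matching is unnecessary and would
  # break the symmetry of the swap
  cfg <- truthConfig(sigma = 20, matchHistograms = FALSE)
  g12 <- scorePair(i1, i2, m1, m2, cfg, transform = affineIdentity())@growthRate
  g21 <- scorePair(i2, i1, m2, m1, cfg, transform = affineIdentity())@growthRate
  expect_lt(abs(g21 - (1 / (1 + g12) - 1)), 0.02)
})

test_that("score is monotone non-decreasing in the merged mask", {
  sc <- smallScene(seed = 34)
  img <- renderScene(sc)
  co <- flattenBackground(img, sigma = 20)
  b <- binarizeImage(co)
  small <- sceneTruthMask(sc)
  large <- RegionMask(matrix(1, 128, 128))
  expect_gte(scoreImage(b, large), scoreImage(b, small))
})

test_that("a 20% mottle increase yields growth 0.20 within tolerance", {
  sc1 <- discScene(size = 256, r = 80, mottleFraction = 0.25,
                   withVessel = FALSE)
  sc2 <- discScene(size = 256, r = 80, mottleFraction = 0.30,
                   withVessel = FALSE)
  expect_equal(sum(sc2@mottleMap) / sum(sc1@mottleMap), 1.2, tolerance = 0.01)
  # photometrically identical renders: growth equals the mottle-count ratio
  rep <- scorePair(renderScene(sc1), renderScene(sc2), sceneTruthMask(sc1),
                   sceneTruthMask(sc2),
                   truthConfig(matchHistograms = FALSE),
                   transform = affineIdentity())
  expect_lt(abs(rep@growthRate - 0.20), 0.03)
  # exact histogram specification equalizes the global distributions and
  # therefore attenuates (but does not reverse) genuine in-mask growth
  repM <- scorePair(renderScene(sc1), renderScene(sc2), sceneTruthMask(sc1),
                    sceneTruthMask(sc2), truthConfig(),
                    transform = affineIdentity())
  expect_gt(repM@growthRate, 0)
  expect_lt(repM@growthRate, rep@growthRate)
})

test_that("score report serialization carries the defining fields", {
  sc <- smallScene(seed = 35)
  img <- renderScene(sc)
  rep <- scorePair(img, img, sceneTruthMask(sc), sceneTruthMask(sc),
                   truthConfig(), transform = affineIdentity())
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  writeScoreReport(rep, jp, cp, referencePath = "a.png", testPath = "b.png")
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$reference_score, rep@referenceScore)
  expect_equal(j$growth_rate, 0)
  d <- utils::read.csv(cp)
  expect_equal(d$merged_mask_area, rep@mergedMaskArea)
})
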