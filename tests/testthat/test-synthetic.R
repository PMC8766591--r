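# Synthetic fundus generator: determinism, layer invariants, rendering
# semantics, and pair construction with known transforms.

test_that("empty scene with flat illumination renders a constant image", {
  z <- matrix(0, 64, 64)
  sc <- SyntheticScene(vesselMap = z, lesionMask = z, mottleMap = z,
                       baseIntensity = 90)
  img <- renderScene(sc)
  expect_true(all(pixels(img) == 90))
})

test_that("scene generation and rendering are seed-deterministic", {
  a <- smallScene(seed = 11)
  b <- smallScene(seed = 11)
  expect_identical(a@vesselMap, b@vesselMap)
  expect_identical(a@lesionMask, b@lesionMask)
  expect_identical(a@mottleMap, b@mottleMap)
  expect_identical(a@illumination, b@illumination)
  expect_identical(pixels(renderScene(a)), pixels(renderScene(b)))
  expect_false(identical(a@lesionMask, smallScene(seed = 12)@lesionMask))
})

test_that("scene layers satisfy their invariants across seeds", {
  for (s in 1:6) {
    sc <- smallScene(seed = s)
    stray <- sc@mottleMap == 1 & !(sc@lesionMask == 1 | sc@vesselMap == 1)
    expect_equal(sum(stray), 0)
    expect_gt(min(sc@illumination), 0)
    expect_lte(max(abs(sc@illumination - 1)), 0.3 + 1e-9)
    expect_true(validObject(sc))
  }
})

test_that("mismatched layer dimensions are rejected with a diagnostic", {
  z <- matrix(0, 64, 64)
  expect_error(
    SyntheticScene(vesselMap = z, lesionMask = matrix(0, 32, 32),
                   mottleMap = z),
    "dimensions")
})

test_that("a 500-pixel mottle scene scores 500 by direct pixel count", {
  size <- 128
  cx <- col(matrix(0, size, size)) - 1; cy <- row(matrix(0, size, size)) - 1
  lesion <- ((cx - 64)^2 + (cy - 64)^2) <= 45^2
  set.seed(5)
  mottle <- matrix(FALSE, size, size)
  mottle[sample(which(lesion), 500)] <- TRUE
  sc <- SyntheticScene(vesselMap = matrix(0, size, size), lesionMask = lesion,
                       mottleMap = mottle, baseIntensity = 100,
                       lesionGain = 0, mottleGain = 40)  # mottle = 1.4x base
  ideal <- sceneIdealIntensities(sc)
  md <- computeMode(ideal, valid = matrix(TRUE, size, size))
  expect_equal(sum(ideal > 1.2 * md), 500)
  # the pipeline (flatten + binarize + count) agrees up to boundary pixels
  pip <- scoreSingle(renderScene(sc), sceneTruthMask(sc), truthConfig())$score
  expect_lte(abs(pip - 500), 0.01 * sum(lesion))
})

test_that("identity pair is bit-identical; known transform maps back", {
  sc <- smallScene(seed = 3)
  pr <- makePair(sc)
  expect_identical(pixels(pr$reference), pixels(pr$aligned))

  tr <- affineFromComponents(translation = c(10, -7))
  pr <- makePair(sc, tr)
  # resample the aligned image back onto the reference grid with the truth
  back <- applyAffine(pr$aligned, tr)
  inner <- validPixels(back)
  inner[c(1:12, 117:128), ] <- FALSE; inner[, c(1:12, 117:128)] <- FALSE
  mae <- mean(abs(pixels(back)[inner] - pixels(pr$reference)[inner]))
  expect_lt(mae, 4)  # interpolation error only
})

test_that("transforms ejecting the lesion and saturating shifts are rejected", {
  sc <- smallScene(seed = 4)
  expect_error(makePair(sc, affineFromComponents(translation = c(200, 0))),
               "lesion")
  expect_error(makePair(sc, gain = 3.5, offset = 120), "saturates")
})

test_that("random affine draws stay inside the stated parameter box", {
  for (s in 1:5) {
    tr <- randomAffine(seed = s)
    L <- tr@matrix[, 1:2]
    expect_true(all(abs(tr@matrix[, 3]) <= 30 + 60))  # translation + recentring
    dt <- det(L)
    expect_gte(dt, 0.9^2 - 0.05); expect_lte(dt, 1.1^2 + 0.05)
  }
})
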