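# Background division and histogram matching.

test_that("a flat field corrects to 1.0 everywhere", {
  img <- FAImage(matrix(100, 96, 96))
  co <- flattenBackground(img, sigma = 10)
  expect_lt(max(abs(pixels(co) - 1)), 1e-6)
})

test_that("correction is invariant to a smooth +/-30% luminance slope", {
  sc <- smallScene(seed = 21, illuminationAmplitude = 0.0001)
  img <- renderScene(sc)
  nx <- (col(pixels(img)) - 1) / 127 - 0.5
  ny <- (row(pixels(img)) - 1) / 127 - 0.5
  ramp <- 1 + 0.3 * nx - 0.25 * ny
  ramped <- FAImage(pmin(pmax(round(pixels(img) * ramp), 0), 255))
  c0 <- pixels(flattenBackground(img, sigma = 20))
  c1 <- pixels(flattenBackground(ramped, sigma = 20))
  interior <- matrix(FALSE, 128, 128)
  interior[21:108, 21:108] <- TRUE
  rms <- sqrt(mean((c1[interior] - c0[interior])^2)) / mean(c0[interior])
  expect_lt(rms, 0.02)
})

test_that("large-sigma limit converges to image / mean(image)", {
  set.seed(22)
  m <- matrix(sample(50:200, 64 * 64, TRUE), 64, 64)
  co <- flattenBackground(FAImage(m), sigma = 2000)
  expect_lt(max(abs(pixels(co) - m / mean(m))), 0.02)
})

test_that("all-zero image warns and returns zeros, not an error", {
  expect_warning(co <- flattenBackground(FAImage(matrix(0, 32, 32))),
                 "all-zero")
  expect_true(all(pixels(co) == 0))
})

test_that("matching an image to itself is an identity up to quantization", {
  co <- flattenBackground(renderScene(smallScene(seed = 23)), sigma = 20)
  out <- matchHistogram(co, co)
  binWidth <- diff(range(pixels(co))) / 256
  expect_lt(max(abs(pixels(out) - pixels(co))), 2 * binWidth)
})

test_that("matching undoes a constant offset (CDF distance <= 2 bins)", {
  co <- flattenBackground(renderScene(smallScene(seed = 24)), sigma = 20)
  shifted <- new("CorrectedImage", pixels = pixels(co) + 0.3,
                 valid = validPixels(co), sigma = co@sigma, source = "")
  out <- matchHistogram(shifted, co)
  q <- seq(0.02, 0.98, by = 0.02)
  dq <- max(abs(quantile(pixels(out), q) - quantile(pixels(co), q)))
  expect_lt(dq, 2 * diff(range(pixels(co))) / 256)
})

test_that("the remap is monotone: pixel ranks are weakly preserved", {
  co <- flattenBackground(renderScene(smallScene(seed = 25)), sigma = 20)
  ref <- flattenBackground(renderScene(smallScene(seed = 26)), sigma = 20)
  out <- matchHistogram(co, ref)
  x <- as.vector(pixels(co)); y <- as.vector(pixels(out))
  o <- order(x)
  expect_true(all(diff(y[o]) >= -1e-12))
  # and the reference itself is untouched
  expect_identical(pixels(ref),
                   pixels(flattenBackground(renderScene(smallScene(seed = 26)),
                                            sigma = 20)))
})

test_that("constant reference maps the test to that constant with a warning", {
  co <- flattenBackground(renderScene(smallScene(seed = 27)), sigma = 20)
  flat <- new("CorrectedImage", pixels = matrix(1, 128, 128),
              valid = matrix(TRUE, 128, 128), sigma = 20, source = "")
  expect_warning(out <- matchHistogram(co, flat), "constant reference")
  expect_true(all(pixels(out) == 1))
})
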