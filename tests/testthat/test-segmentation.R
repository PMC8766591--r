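# Segmentation: confusion-table metrics, mask prediction semantics, and
# small-scale training behaviour. Full-scale quality lives in the
# acceptance suite.

test_that("sensitivity/specificity match a hand-counted confusion table", {
  truth <- matrix(0, 4, 4); truth[c(1, 2, 3, 5, 6, 9)] <- 1   # 6 positives
  pred <- matrix(0, 4, 4); pred[c(1, 2, 3, 5, 6)] <- 1        # 5 hits
  pred[c(11, 12)] <- 1                                        # 2 false pos
  ss <- sensitivitySpecificity(pred, truth)
  expect_equal(unname(ss["sensitivity"]), 5 / 6)
  expect_equal(unname(ss["specificity"]), 8 / 10)
})

test_that("perfect and inverted predictions give (1,1) and (0,0)", {
  set.seed(41)
  truth <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(unname(sensitivitySpecificity(truth, truth)), c(1, 1))
  expect_equal(unname(sensitivitySpecificity(1 - truth, truth)), c(0, 0))
})

test_that("undefined denominators give NA, and transposition is neutral", {
  allZero <- matrix(0, 4, 4)
  ss <- sensitivitySpecificity(allZero, allZero)
  expect_true(is.na(ss["sensitivity"]))   # no positives anywhere
  expect_equal(unname(ss["specificity"]), 1)

  set.seed(42)
  truth <- matrix(rbinom(48, 1, 0.5), 6, 8)
  pred <- matrix(rbinom(48, 1, 0.5), 6, 8)
  expect_equal(sensitivitySpecificity(pred, truth),
               sensitivitySpecificity(t(pred), t(truth)))
  expect_error(sensitivitySpecificity(pred, matrix(0, 8, 6)), "differ")
})

test_that("training is seed-deterministic and the loss decreases", {
  scenes <- lapply(1:4, function(s) smallScene(seed = 50 + s, size = 64))
  imgs <- lapply(scenes, renderScene)
  msks <- lapply(scenes, sceneTruthMask)
  cfg <- segmenterConfig(epochs = 6, seed = 9, downsample = 2)
  m1 <- trainSegmenter(imgs, msks, cfg)
  m2 <- trainSegmenter(imgs, msks, cfg)
  expect_identical(m1@trainingLoss, m2@trainingLoss)
  expect_lt(tail(m1@trainingLoss, 1), m1@trainingLoss[1])
  expect_identical(predictProbability(m1, imgs[[1]]),
                   predictProbability(m2, imgs[[1]]))
})

test_that("degenerate training input is rejected", {
  sc <- smallScene(seed = 55, size = 64)
  img <- renderScene(sc); msk <- sceneTruthMask(sc)
  expect_error(trainSegmenter(list(img), list(msk)), "at least 2")
  expect_error(trainSegmenter(list(img, img), list(msk)), "pair up")
  bad <- RegionMask(matrix(0, 32, 32))
  expect_error(trainSegmenter(list(img, img), list(msk, bad)), "mismatch")
})

test_that("a model fit to background-only scenes predicts almost nothing", {
  z <- matrix(0, 64, 64)
  sc <- SyntheticScene(vesselMap = z, lesionMask = z, mottleMap = z,
                       baseIntensity = 95)
  img <- renderScene(sc)
  msk <- sceneTruthMask(sc)
  mod <- trainSegmenter(list(img, img), list(msk, msk),
                        segmenterConfig(epochs = 15, seed = 3, downsample = 2))
  pred <- predictMask(mod, img)
  expect_lte(mean(pixels(pred)), 0.01)
})

test_that("probability threshold semantics: floor, ceiling, monotonicity", {
  scenes <- lapply(1:3, function(s) smallScene(seed = 60 + s, size = 64))
  imgs <- lapply(scenes, renderScene)
  msks <- lapply(scenes, sceneTruthMask)
  mod <- trainSegmenter(imgs[1:2], msks[1:2],
                        segmenterConfig(epochs = 2, seed = 4, downsample = 2))
  img <- imgs[[3]]
  expect_true(all(pixels(predictMask(mod, img, 0)) == 1))
  expect_true(all(pixels(predictMask(mod, img, 1 + 1e-9)) == 0))
  lo <- predictMask(mod, img, 0.3)
  hi <- predictMask(mod, img, 0.6)
  expect_true(all(pixels(hi) <= pixels(lo)))  # raising never adds pixels
})

test_that("segmenter save/load round-trips weights and predictions", {
  scenes <- lapply(1:2, function(s) smallScene(seed = 70 + s, size = 64))
  imgs <- lapply(scenes, renderScene)
  msks <- lapply(scenes, sceneTruthMask)
  mod <- trainSegmenter(imgs, msks,
                        segmenterConfig(epochs = 2, seed = 5, downsample = 2))
  p <- tempfile(fileext = ".rds")
  saveSegmenter(mod, p)
  back <- loadSegmenter(p)
  expect_identical(predictProbability(back, imgs[[1]]),
                   predictProbability(mod, imgs[[1]]))
})
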