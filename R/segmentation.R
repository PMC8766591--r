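## Abnormal-region segmentation: a small U-net-style encoder-decoder
## trained on (image, mask) pairs, plus the pixelwise sensitivity /
## specificity evaluation. The mask source is pluggable: a trained model,
## an annotation file, or synthetic ground truth - the scoring pipeline is
## fully exercisable without any trained model.

#' Training / architecture configuration for the segmenter
#'
#' @param depth number of resolution levels including the bottleneck (3).
#' @param baseChannels channels at the finest level, doubling per level (8).
#' @param epochs training epochs (30).
#' @param learningRate Adam learning rate (1e-3).
#' @param seed RNG seed controlling initialization and shuffling.
#' @param downsample integer factor by which images are subsampled before
#'   entering the network (default 8: the canonical 496 grid becomes 62);
#'   predictions are upsampled back to the input grid. Lesions span tens of
#'   pixels even at this scale, and the coarser grid widens the effective
#'   receptive field while keeping single-CPU training fast.
#' @param loss "bce" (binary cross-entropy, default) or "dice".
#' @param posWeight weight on positive (abnormal) pixels in the BCE loss (1).
#' @return a named list of class `segmenter_config`.
#' @export
segmenterConfig <- function(depth = 3, baseChannels = 8, epochs = 30,
                            learningRate = 1e-3, seed = 1, downsample = 8,
                            loss = c("bce", "dice"), posWeight = 1) {
  loss <- match.arg(loss)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 epochs = as.integer(epochs), learningRate = learningRate,
                 seed = as.integer(seed), downsample = as.integer(downsample),
                 loss = loss, posWeight = posWeight),
            class = "segmenter_config")
}

.downsampleBy <- function(m, f) {
  if (f <= 1) return(m)
  m[seq(1, nrow(m), by = f), seq(1, ncol(m), by = f), drop = FALSE]
}

.prepareTrainingPair <- function(image, mask, f) {
  im <- .downsampleBy(if (is(image, "FAImage")) pixels(image) else image, f)
  ms <- .downsampleBy(if (is(mask, "RegionMask")) pixels(mask) else mask, f)
  ## network grids must pool twice: trim to a multiple of 4
  H <- (nrow(im) %/% 4L) * 4L; W <- (ncol(im) %/% 4L) * 4L
  list(x = matrix(as.vector(im[1:H, 1:W]) / 255, ncol = 1),
       y = as.vector(ms[1:H, 1:W]), H = H, W = W)
}

.bceLossGrad <- function(logits, y, posWeight = 1) {
  n <- length(y)
  wts <- ifelse(y == 1, posWeight, 1)
  ## numerically stable BCE with logits
  loss <- sum(wts * (pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))) /
    sum(wts)
  p <- stats::plogis(logits)
  grad <- wts * (p - y) / sum(wts)
  list(loss = loss, grad = grad)
}

.diceLossGrad <- function(logits, y, eps = 1) {
  p <- stats::plogis(logits)
  num <- 2 * sum(p * y) + eps
  den <- sum(p) + sum(y) + eps
  loss <- 1 - num / den
  dp <- -(2 * y * den - num) / den^2
  list(loss = loss, grad = dp * p * (1 - p))
}

#' Train the abnormal-region segmenter
#'
#' Stochastic training (one image per step, shuffled each epoch) with Adam;
#' reproducible from `config$seed`. Images are scaled to \[0, 1\] and
#' subsampled by `config$downsample` before entering the network.
#'
#' @param images list of [FAImage-class] objects (or matrices).
#' @param masks list of matching [RegionMask-class] truth masks.
#' @param config a [segmenterConfig()].
#' @param logPath optional CSV path receiving the per-epoch loss log.
#' @param verbose print per-epoch loss.
#' @return a [SegmenterModel-class].
#' @export
trainSegmenter <- function(images, masks, config = segmenterConfig(),
                           logPath = NULL, verbose = FALSE) {
  if (length(images) < 2) stop("need at least 2 training pairs")
  if (length(images) != length(masks)) stop("images and masks must pair up")
  pairs <- mapply(function(im, ms) {
    di <- dim(if (is(im, "FAImage")) pixels(im) else im)
    dm <- dim(if (is(ms, "RegionMask")) pixels(ms) else ms)
    if (!identical(di, dm)) stop("image/mask shape mismatch")
    .prepareTrainingPair(im, ms, config$downsample)
  }, images, masks, SIMPLIFY = FALSE)

  withSeed(config$seed, {
    w <- .initWeights(config$depth, config$baseChannels)
    state <- list(t = 0L, m = list(), v = list())
    epochLoss <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      losses <- numeric(length(pairs))
      for (i in seq_along(ord)) {
        p <- pairs[[ord[i]]]
        fw <- .netForward(w, p$x, p$H, p$W, config$depth, keep = TRUE)
        lg <- if (config$loss == "bce")
          .bceLossGrad(fw$logits, p$y, config$posWeight)
        else .diceLossGrad(fw$logits, p$y)
        losses[i] <- lg$loss
        gr <- .netBackward(w, fw$cache, lg$grad, config$depth)
        upd <- .adamStep(w, gr, state, config$learningRate)
        w <- upd$w; state <- upd$state
      }
      epochLoss[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs,
                        epochLoss[ep]))
    }
    if (!is.null(logPath))
      utils::write.csv(data.frame(epoch = seq_along(epochLoss),
                                  loss = epochLoss),
                       logPath, row.names = FALSE)
    new("SegmenterModel", weights = w, config = unclass(config),
        trainingLoss = epochLoss)
  })
}

#' Per-pixel abnormality probability map
#'
#' Deterministic inference; the coarse-grid output is nearest-neighbour
#' upsampled back to the input grid.
#' @param model a [SegmenterModel-class].
#' @param image an [FAImage-class] (or numeric matrix in \[0, 255\]).
#' @return numeric matrix of probabilities, same shape as the input.
#' @export
predictProbability <- function(model, image) {
  m <- if (is(image, "FAImage")) pixels(image) else image
  cfg <- model@config
  p <- .prepareTrainingPair(m, m * 0, cfg$downsample)
  fw <- .netForward(model@weights, p$x, p$H, p$W, cfg$depth, keep = FALSE)
  coarse <- matrix(stats::plogis(fw$logits), p$H, p$W)
  resizeNearest(coarse, nrow(m), ncol(m))
}

#' Predict the abnormal-region mask of an FA image
#'
#' @param model a [SegmenterModel-class].
#' @param image an [FAImage-class].
#' @param probThreshold probability cutoff; a pixel is abnormal iff its
#'   probability is `>= probThreshold` (so 0 gives an all-ones mask and any
#'   threshold above 1 an all-zeros mask). Default 0.5.
#' @return a [RegionMask-class] with `source = "model"`.
#' @export
predictMask <- function(model, image, probThreshold = 0.5) {
  pr <- predictProbability(model, image)
  RegionMask(pr >= probThreshold, source = "model",
             probThreshold = probThreshold)
}

#' Pixelwise sensitivity and specificity of a predicted mask
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP), counted over
#' the whole image. Undefined ratios (empty denominator) are reported as
#' `NA`, not 0.
#' @param pred predicted [RegionMask-class] (or 0/1 matrix).
#' @param truth reference [RegionMask-class] (or 0/1 matrix).
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivitySpecificity <- function(pred, truth) {
  p <- if (is(pred, "RegionMask")) pixels(pred) else pred
  t <- if (is(truth, "RegionMask")) pixels(truth) else truth
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  tp <- sum(p == 1 & t == 1); fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0); fp <- sum(p == 1 & t == 0)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Dice overlap coefficient between two binary masks
#' @param a,b [RegionMask-class] objects or 0/1 matrices.
#' @return Dice coefficient in \[0, 1\] (`NA` if both masks are empty).
#' @export
diceCoefficient <- function(a, b) {
  pa <- if (is(a, "RegionMask")) pixels(a) else a
  pb <- if (is(b, "RegionMask")) pixels(b) else b
  s <- sum(pa == 1) + sum(pb == 1)
  if (s == 0) return(NA_real_)
  2 * sum(pa == 1 & pb == 1) / s
}

#' Save / load a trained segmenter
#'
#' Weights, config and the training-loss trace in a single RDS file.
#' @param model a [SegmenterModel-class].
#' @param path file path.
#' @return `path` invisibly; `loadSegmenter` returns the model.
#' @export
saveSegmenter <- function(model, path) {
  saveRDS(list(weights = model@weights, config = model@config,
               trainingLoss = model@trainingLoss), path)
  invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
  x <- readRDS(path)
  new("SegmenterModel", weights = x$weights, config = x$config,
      trainingLoss = x$trainingLoss)
}
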