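## Shared numeric helpers: seeded evaluation, reflected Gaussian blur,
## nearest-neighbour resampling.

.pkgCache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators and RANSAC do not disturb
#' the caller's RNG state while staying fully reproducible.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## reflect an out-of-range 1-based index into [1, n] ('mirror' boundary,
## period 2n: ... 2 1 | 1 2 ... n | n ... )
reflectIndex <- function(p, n) {
  m <- ((p - 1) %% (2 * n) + 2 * n) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

## Dense n x n one-dimensional Gaussian convolution operator with reflected
## boundaries, cached by (n, sigma). Blur of a matrix X is K_r X K_c'.
gaussianKernelMatrix <- function(n, sigma) {
  key <- sprintf("gk_%d_%g", n, sigma)
  if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq(-r, r)) {
    j <- reflectIndex(i + k, n)
    ij <- cbind(i, j)
    K[ij] <- K[ij] + w[k + r + 1]
  }
  .pkgCache[[key]] <- K
  K
}

#' Gaussian blur with reflected boundaries
#'
#' Separable Gaussian filter implemented as two dense banded-operator matrix
#' products (exact reflection handling, BLAS-backed), matching the behaviour
#' expected of the sigma = 70 px background estimate.
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix, same shape.
#' @export
gaussianBlurReflect <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  Kr <- gaussianKernelMatrix(nrow(x), sigma)
  Kc <- gaussianKernelMatrix(ncol(x), sigma)
  Kr %*% x %*% t(Kc)
}

#' Nearest-neighbour (order-0) resampling
#'
#' Maps each output pixel centre to the nearest input pixel; introduces no
#' new gray levels, so binary masks survive rescaling unchanged.
#' @param x numeric matrix.
#' @param nrowOut,ncolOut output dimensions.
#' @return resampled matrix.
#' @export
resizeNearest <- function(x, nrowOut, ncolOut) {
  stopifnot(is.matrix(x), nrowOut >= 1, ncolOut >= 1)
  ri <- pmin(nrow(x), floor((seq_len(nrowOut) - 0.5) * nrow(x) / nrowOut) + 1)
  ci <- pmin(ncol(x), floor((seq_len(ncolOut) - 0.5) * ncol(x) / ncolOut) + 1)
  x[ri, ci, drop = FALSE]
}

## small deterministic string hash for provenance stamps (polynomial mod
## 2^31 - 1, hex-printed)
provenanceHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(paste(s, collapse = "\n"))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

## derive a bounded child seed from a base seed and a stream id
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}
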