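## Native encoder-decoder convolutional network (U-net family).
##
## Feature maps are stored as (H*W) x C matrices in column-major image
## order; 3x3 convolutions use im2col gathers followed by BLAS matrix
## products, which keeps CPU training of the small default network within a
## desk-scale budget. Only what the segmenter needs is implemented: 3x3 and
## 1x1 convolutions, ReLU, 2x2 max-pool, nearest 2x upsampling, channel
## concatenation, sigmoid/BCE loss, Adam.

.gridKey <- function(H, W) sprintf("g_%d_%d", H, W)

## cached index structures for an H x W grid
.gridIdx <- function(H, W) {
  key <- .gridKey(H, W)
  if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  r <- rep(seq_len(H), times = W); c <- rep(seq_len(W), each = H)
  im2col <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    im2col[, k] <- (c + dc) * Hp + (r + 1L + dr)
  }
  interior <- as.vector(im2col[, 5L])  # centre offset = the unpadded cells
  g <- list(im2col = im2col, interior = interior, Hp = Hp, Wp = Wp)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    r2 <- rep(seq_len(H2), times = W2); c2 <- rep(seq_len(W2), each = H2)
    tl <- (2L * c2 - 2L) * H + (2L * r2 - 1L)
    g$pool <- cbind(tl, tl + 1L, tl + H, tl + H + 1L)
    ## nearest x2 upsample: source row index for every fine pixel
    rf <- rep(seq_len(H), times = W); cf <- rep(seq_len(W), each = H)
    g$up <- ((cf + 1L) %/% 2L - 1L) * H2 + (rf + 1L) %/% 2L
  }
  .pkgCache[[key]] <- g
  g
}

## weight layout is offset-major: rows ((k-1)*Cin+1):(k*Cin) of the
## (9*Cin) x Cout matrix hold the Cin x Cout slice for circle offset k,
## so the convolution is 9 gathers + 9 BLAS products with no reshaping
.conv3Forward <- function(x, W8, b, H, Wd) {
  g <- .gridIdx(H, Wd)
  Cin <- ncol(x)
  xp <- matrix(0, g$Hp * g$Wp, Cin)
  xp[g$interior, ] <- x
  y <- matrix(rep(b, each = H * Wd), H * Wd, length(b))
  for (k in 1:9) {
    rows <- ((k - 1L) * Cin + 1L):(k * Cin)
    y <- y + xp[g$im2col[, k], , drop = FALSE] %*% W8[rows, , drop = FALSE]
  }
  list(y = y, xp = xp, Cin = Cin, H = H, W = Wd)
}

## gradient w.r.t. the conv weights, from the cached padded input
.conv3GradW <- function(cv, dy) {
  g <- .gridIdx(cv$H, cv$W)
  dW <- matrix(0, 9L * cv$Cin, ncol(dy))
  for (k in 1:9) {
    rows <- ((k - 1L) * cv$Cin + 1L):(k * cv$Cin)
    dW[rows, ] <- crossprod(cv$xp[g$im2col[, k], , drop = FALSE], dy)
  }
  list(W = dW, b = colSums(dy))
}

.conv3BackwardX <- function(dy, W8, H, Wd, Cin) {
  g <- .gridIdx(H, Wd)
  dxp <- matrix(0, g$Hp * g$Wp, Cin)
  for (k in 1:9) {
    rows <- ((k - 1L) * Cin + 1L):(k * Cin)
    idx <- g$im2col[, k]
    dxp[idx, ] <- dxp[idx, , drop = FALSE] + dy %*% t(W8[rows, , drop = FALSE])
  }
  dxp[g$interior, , drop = FALSE]
}

.pool2Forward <- function(x, H, Wd) {
  g <- .gridIdx(H, Wd)
  C <- ncol(x); n2 <- nrow(g$pool)
  y <- matrix(0, n2, C); arg <- matrix(0L, n2, C)
  for (ch in seq_len(C)) {
    v <- matrix(x[g$pool, ch], n2, 4L)
    a <- max.col(v, ties.method = "first")
    y[, ch] <- v[cbind(seq_len(n2), a)]
    arg[, ch] <- g$pool[cbind(seq_len(n2), a)]
  }
  list(y = y, arg = arg)
}

.pool2Backward <- function(dy, arg, H, Wd) {
  dx <- matrix(0, H * Wd, ncol(dy))
  for (ch in seq_len(ncol(dy))) dx[arg[, ch], ch] <- dy[, ch]
  dx
}

.up2Forward <- function(x, Hc, Wc) {
  g <- .gridIdx(2L * Hc, 2L * Wc)
  x[g$up, , drop = FALSE]
}

.up2Backward <- function(dy, Hc, Wc) {
  g <- .gridIdx(2L * Hc, 2L * Wc)
  rowsum(dy, group = g$up)  # groups 1..Hc*Wc all present, sorted order
}

## He-normal initialization for a 3x3 (or 1x1) conv
.initConv <- function(kin, cout, k = 9L) {
  list(W = matrix(stats::rnorm(k * kin * cout, sd = sqrt(2 / (k * kin))),
                  k * kin, cout),
       b = rep(0, cout))
}

## build the weight list for a given depth / base-channel count
.initWeights <- function(depth, base, inChannels = 1L) {
  ch <- base * 2^(0:(depth - 1))
  w <- list(enc = vector("list", depth - 1), dec = vector("list", depth - 1))
  cin <- inChannels
  for (l in seq_len(depth - 1)) {
    w$enc[[l]] <- list(.initConv(cin, ch[l]), .initConv(ch[l], ch[l]))
    cin <- ch[l]
  }
  w$bott <- list(.initConv(cin, ch[depth]), .initConv(ch[depth], ch[depth]))
  for (l in rev(seq_len(depth - 1))) {
    w$dec[[l]] <- list(
      reduce = .initConv(ch[l + 1], ch[l]),
      conv1 = .initConv(2L * ch[l], ch[l]),
      conv2 = .initConv(ch[l], ch[l]))
  }
  w$out <- .initConv(ch[1], 1L, k = 1L)
  w
}

## forward pass; returns logits and (optionally) every tensor needed for
## backprop
.netForward <- function(w, x, H, W, depth, keep = FALSE) {
  cache <- list(sizes = list(), enc = list(), x = x)
  a <- x; h <- H; wd <- W
  for (l in seq_len(depth - 1)) {
    c1 <- .conv3Forward(a, w$enc[[l]][[1]]$W, w$enc[[l]][[1]]$b, h, wd)
    r1 <- pmax(c1$y, 0)
    c2 <- .conv3Forward(r1, w$enc[[l]][[2]]$W, w$enc[[l]][[2]]$b, h, wd)
    r2 <- pmax(c2$y, 0)
    p <- .pool2Forward(r2, h, wd)
    cache$enc[[l]] <- if (keep)
      list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, arg = p$arg, h = h, w = wd)
    else list(r2 = r2)
    cache$sizes[[l]] <- c(h, wd)
    a <- p$y; h <- h %/% 2L; wd <- wd %/% 2L
  }
  cb1 <- .conv3Forward(a, w$bott[[1]]$W, w$bott[[1]]$b, h, wd)
  rb1 <- pmax(cb1$y, 0)
  cb2 <- .conv3Forward(rb1, w$bott[[2]]$W, w$bott[[2]]$b, h, wd)
  rb2 <- pmax(cb2$y, 0)
  if (keep) cache$bott <- list(c1 = cb1, r1 = rb1, c2 = cb2, r2 = rb2,
                               h = h, w = wd, input = a)
  a <- rb2
  dec <- list()
  for (l in rev(seq_len(depth - 1))) {
    hu <- 2L * h; wu <- 2L * wd
    up <- .up2Forward(a, h, wd)
    cr <- .conv3Forward(up, w$dec[[l]]$reduce$W, w$dec[[l]]$reduce$b, hu, wu)
    rr <- pmax(cr$y, 0)
    cat_in <- cbind(rr, cache$enc[[l]]$r2)
    c1 <- .conv3Forward(cat_in, w$dec[[l]]$conv1$W, w$dec[[l]]$conv1$b, hu, wu)
    r1 <- pmax(c1$y, 0)
    c2 <- .conv3Forward(r1, w$dec[[l]]$conv2$W, w$dec[[l]]$conv2$b, hu, wu)
    r2 <- pmax(c2$y, 0)
    if (keep) dec[[l]] <- list(cr = cr, rr = rr, c1 = c1, r1 = r1,
                               c2 = c2, r2 = r2, h = hu, w = wu,
                               hc = h, wc = wd, input = a)
    a <- r2; h <- hu; wd <- wu
  }
  logits <- a %*% w$out$W + rep(w$out$b, each = nrow(a))
  if (keep) {
    cache$dec <- dec
    cache$preOut <- a
  }
  list(logits = as.vector(logits), cache = if (keep) cache else NULL)
}

## full backward pass; returns gradients with the same structure as weights
.netBackward <- function(w, cache, dlogits, depth) {
  gr <- list(enc = vector("list", depth - 1), dec = vector("list", depth - 1),
             bott = NULL, out = NULL)
  a <- cache$preOut
  gr$out <- list(W = crossprod(a, matrix(dlogits, ncol = 1)),
                 b = sum(dlogits))
  da <- matrix(dlogits, ncol = 1) %*% t(w$out$W)
  dskip <- vector("list", depth - 1)
  for (l in seq_len(depth - 1)) {
    dc <- cache$dec[[l]]
    d2 <- da * (dc$c2$y > 0)
    gr$dec[[l]]$conv2 <- .conv3GradW(dc$c2, d2)
    d1in <- .conv3BackwardX(d2, w$dec[[l]]$conv2$W, dc$h, dc$w,
                            ncol(dc$r1))
    d1 <- d1in * (dc$c1$y > 0)
    gr$dec[[l]]$conv1 <- .conv3GradW(dc$c1, d1)
    dcat <- .conv3BackwardX(d1, w$dec[[l]]$conv1$W, dc$h, dc$w,
                            2L * ncol(dc$rr))
    nrr <- ncol(dc$rr)
    drr <- dcat[, seq_len(nrr), drop = FALSE]
    dskip[[l]] <- dcat[, nrr + seq_len(nrr), drop = FALSE]
    dr <- drr * (dc$cr$y > 0)
    gr$dec[[l]]$reduce <- .conv3GradW(dc$cr, dr)
    dup <- .conv3BackwardX(dr, w$dec[[l]]$reduce$W, dc$h, dc$w,
                           ncol(dc$input))
    da <- .up2Backward(dup, dc$hc, dc$wc)
  }
  bt <- cache$bott
  d2 <- da * (bt$c2$y > 0)
  gr$bott <- list(NULL, NULL)
  gr$bott[[2]] <- .conv3GradW(bt$c2, d2)
  d1in <- .conv3BackwardX(d2, w$bott[[2]]$W, bt$h, bt$w, ncol(bt$r1))
  d1 <- d1in * (bt$c1$y > 0)
  gr$bott[[1]] <- .conv3GradW(bt$c1, d1)
  da <- .conv3BackwardX(d1, w$bott[[1]]$W, bt$h, bt$w, ncol(bt$input))
  for (l in rev(seq_len(depth - 1))) {
    ec <- cache$enc[[l]]
    dpool <- .pool2Backward(da, ec$arg, ec$h, ec$w)
    dr2 <- dpool + dskip[[l]]
    d2 <- dr2 * (ec$c2$y > 0)
    gr$enc[[l]] <- list(NULL, NULL)
    gr$enc[[l]][[2]] <- .conv3GradW(ec$c2, d2)
    d1in <- .conv3BackwardX(d2, w$enc[[l]][[2]]$W, ec$h, ec$w, ncol(ec$r1))
    d1 <- d1in * (ec$c1$y > 0)
    gr$enc[[l]][[1]] <- .conv3GradW(ec$c1, d1)
    if (l > 1)
      da <- .conv3BackwardX(d1, w$enc[[l]][[1]]$W, ec$h, ec$w,
                            ncol(cache$enc[[l - 1]]$r2))
  }
  gr
}

## flatten/unflatten weight structure for the optimizer
.flattenW <- function(w) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x) && !is.null(x$W)) {
      out[[paste0(prefix, ".W")]] <<- x$W
      out[[paste0(prefix, ".b")]] <<- x$b
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste0(prefix, "/", nm))
      }
    }
  }
  walk(w, "w")
  out
}

.adamStep <- function(w, gr, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  fw <- .flattenW(w); fg <- .flattenW(gr)
  for (nm in names(fw)) {
    g <- fg[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    fw[[nm]] <- fw[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  ## write the updated tensors back into the nested structure
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$W)) {
      i <<- i + 1L; x$W <- fw[[2L * i - 1L]]; x$b <- as.vector(fw[[2L * i]])
      x
    } else if (is.list(x)) {
      for (j in seq_along(x)) if (is.list(x[[j]])) x[[j]] <- rebuild(x[[j]])
      x
    } else x
  }
  list(w = rebuild(w), state = state)
}
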