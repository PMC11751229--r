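# Minimal layer primitives with explicit forward/backward passes.
# Feature tensors are (C, H, W, B) arrays; the channel axis is contiguous,
# so pointwise convolutions are direct BLAS products and the batch-norm /
# ReLU kernels stream over the block once in C++.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## ---- pointwise (1x1) convolution -------------------------------------------

pw_fwd <- function(x, W) {
  d <- dim(x)
  y <- .pw_fwd(x, W)
  dim(y) <- c(nrow(W), d[2], d[3], d[4])
  y
}

pw_bwd <- function(x, W, gy) {
  g <- .pw_bwd(x, W, gy)
  dim(g$gx) <- dim(x)
  g
}

## ---- depthwise 3x3 (compiled kernels) --------------------------------------

dw3_fwd <- function(x, k, stride, bias = NULL) {
  d <- dim(x)
  if (is.null(bias)) bias <- numeric(d[1])
  y <- .dw3_fwd(x, k, bias, d[1], d[2], d[3], d[4], stride)
  ho <- (d[2] - 1L) %/% stride + 1L
  wo <- (d[3] - 1L) %/% stride + 1L
  dim(y) <- c(d[1], ho, wo, d[4])
  y
}

dw3_bwd <- function(x, k, gy, stride) {
  d <- dim(x)
  g <- .dw3_bwd(x, k, gy, d[1], d[2], d[3], d[4], stride)
  dim(g$gx) <- d
  dim(g$gk) <- c(d[1], 9L)
  g
}

## ---- depthwise 1x1 ----------------------------------------------------------

dw1_fwd <- function(x, k, stride) {
  d <- dim(x)
  y <- .dw1_fwd(x, k, d[1], d[2], d[3], d[4], stride)
  ho <- (d[2] - 1L) %/% stride + 1L
  wo <- (d[3] - 1L) %/% stride + 1L
  dim(y) <- c(d[1], ho, wo, d[4])
  y
}

dw1_bwd <- function(x, k, gy, stride) {
  d <- dim(x)
  g <- .dw1_bwd(x, k, gy, d[1], d[2], d[3], d[4], stride)
  dim(g$gx) <- d
  g
}

## ---- batch normalization ----------------------------------------------------

bn_fwd <- function(x, g, b, rm, rv, train) {
  r <- .bn_fwd(x, g, b, rm, rv, train, BN_MOMENTUM, BN_EPS)
  dim(r$y) <- dim(x)
  list(y = r$y, cache = list(x = x, mu = r$mu, invstd = r$invstd, train = train),
       rm = r$rm, rv = r$rv)
}

bn_bwd <- function(cache, g, gy) {
  r <- .bn_bwd(cache$x, cache$mu, cache$invstd, g, gy, cache$train)
  dim(r$gx) <- dim(gy)
  r
}

bn_relu_fwd <- function(x, g, b, rm, rv, train) {
  r <- .bn_relu_fwd(x, g, b, rm, rv, train, BN_MOMENTUM, BN_EPS)
  dim(r$y) <- dim(x)
  list(y = r$y, cache = list(x = x, mu = r$mu, invstd = r$invstd,
                             y = r$y, train = train),
       rm = r$rm, rv = r$rv)
}

bn_relu_bwd <- function(cache, g, gy) {
  r <- .bn_relu_bwd(cache$x, cache$mu, cache$invstd, g, cache$y, gy,
                    cache$train)
  dim(r$gx) <- dim(gy)
  r
}

## ---- activations ------------------------------------------------------------

relu_fwd <- function(x) {
  y <- .relu_fwd(x)
  dim(y) <- dim(x)
  y
}

relu_bwd <- function(y, gy) {
  gx <- .relu_bwd(y, gy)
  dim(gx) <- dim(gy)
  gx
}

## ---- global average pooling -------------------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  list(emb = .gap_fwd(x, d[1], d[2] * d[3], d[4]), hw = c(d[2], d[3]))
}

gap_bwd <- function(gemb, hw, B) {
  n <- hw[1] * hw[2]
  gx <- gemb[, rep(seq_len(B), each = n), drop = FALSE] / n
  dim(gx) <- c(nrow(gemb), hw[1], hw[2], B)
  gx
}

## ---- linear head ------------------------------------------------------------

lin_fwd <- function(emb, W, b) W %*% emb + b

lin_bwd <- function(emb, W, glog) {
  list(gW = tcrossprod(glog, emb), gb = rowSums(glog),
       gemb = crossprod(W, glog))
}
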