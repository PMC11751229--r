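# Four-stage re-parameterizable encoder: shapes, determinism, fusion,
# parameter counting, and gradient correctness.

test_that("initialization is deterministic and tap shapes follow the stride plan", {
  e1 <- build_encoder(encoder_config(), seed = 5L)
  e2 <- build_encoder(encoder_config(), seed = 5L)
  expect_identical(e1$par, e2$par)
  x32 <- array(runif(1 * 32 * 32 * 2), c(1, 32, 32, 2))
  f32 <- forward_features(e1, x32)
  expect_equal(dim(f32$tap)[2:3], c(4L, 4L))     # stride 8 after 3 stages
  expect_equal(dim(f32$embedding), c(256L, 2L))
  x112 <- array(runif(1 * 112 * 112 * 1), c(1, 112, 112, 1))
  f112 <- forward_features(e1, x112)
  expect_equal(dim(f112$tap)[2:3], c(14L, 14L))
  expect_error(forward_features(e1, array(0, c(1, 30, 30, 1))), "divisible")
  expect_error(forward_features(e1, array(0, c(2, 32, 32, 1))), "channel")
})

test_that("inference-mode forward is finite, batch-independent, batch-shaped", {
  enc <- build_encoder(encoder_config(stage_widths = c(6L, 12L, 24L, 48L)),
                       seed = 2L)
  z <- forward_features(enc, array(0, c(1, 32, 32, 1)))
  expect_true(all(is.finite(z$tap)) && all(is.finite(z$embedding)))
  set.seed(8)
  xb <- array(runif(1 * 32 * 32 * 5), c(1, 32, 32, 5))
  fb <- forward_features(enc, xb)
  f1 <- forward_features(enc, xb[, , , 3L, drop = FALSE])
  expect_lt(max(abs(fb$embedding[, 3L] - f1$embedding[, 1L])), 1e-6)
  expect_equal(dim(fb$embedding)[2], 5L)
})

test_that("re-parameterization fusion reproduces the branched encoder", {
  enc <- build_encoder(encoder_config(stage_widths = c(6L, 12L, 24L, 48L)),
                       seed = 3L)
  # accumulate non-trivial running statistics first
  set.seed(1)
  for (i in 1:4) {
    fw <- spemix:::enc_forward(enc, array(runif(1 * 32 * 32 * 8), c(1, 32, 32, 8)),
                               train = TRUE)
    enc$buf <- fw$buf
  }
  fused <- fuse_reparam(enc)
  expect_lt(count_parameters(fused), count_parameters(enc))
  set.seed(2)
  worst <- 0
  for (i in 1:100) {
    x <- array(runif(1 * 32 * 32 * 1), c(1, 32, 32, 1))
    a <- forward_features(enc, x)
    b <- forward_features(fused, x)
    worst <- max(worst, max(abs(a$embedding - b$embedding)),
                 max(abs(a$tap - b$tap)))
  }
  expect_lt(worst, 1e-4)
  expect_warning(fuse_reparam(fused), "already fused")
})

test_that("fusing a block with zeroed conv branches leaves the identity kernel", {
  enc <- build_encoder(encoder_config(stage_widths = c(4L, 4L, 4L, 4L),
                                      stage_depths = c(1L, 1L, 2L, 1L)),
                       seed = 1L)
  p <- "s3b2"  # stride-1 block with an identity branch
  enc$par[[paste0(p, ".dw.k3")]][] <- 0
  enc$par[[paste0(p, ".dw.k1")]][] <- 0
  fused <- fuse_reparam(enc)
  k <- fused$par[[paste0(p, ".dw.k3f")]]
  expect_equal(k[, 5L], rep(1, 4), tolerance = 1e-4)     # centre tap
  expect_true(all(abs(k[, -5L]) == 0))
  expect_equal(fused$par[[paste0(p, ".dw.bf")]], rep(0, 4), tolerance = 1e-6)
})

test_that("count_parameters matches independent enumeration", {
  expect_equal(count_parameters(list(matrix(0, 5, 10), numeric(5))), 55L)
  expect_equal(count_parameters(), 0L)
  enc <- build_encoder(encoder_config(stage_widths = c(6L, 12L, 24L, 48L)),
                       seed = 1L)
  oracle <- sum(vapply(enc$par, length, integer(1)))
  expect_equal(count_parameters(enc), oracle)
})

test_that("encoder backward matches finite differences", {
  set.seed(42)
  ns <- asNamespace("spemix")
  enc <- build_encoder(tiny_encoder(), seed = 3L)
  x <- array(runif(1 * 16 * 16 * 2), c(1, 16, 16, 2))
  R <- matrix(rnorm(10 * 2), 10, 2)
  lossfun <- function(enc, x) sum(ns$enc_forward(enc, x, train = TRUE)$emb * R)
  fw <- ns$enc_forward(enc, x, train = TRUE, keep_cache = TRUE)
  bk <- ns$enc_backward(enc, fw, R)
  eps <- 1e-5
  for (nm in c("s1b1.dw.k3", "s2b1.pw1.W", "s3b2.dw.bnid.g", "s4b1.pw2.bn.b")) {
    for (ii in sample(length(enc$par[[nm]]), 2L)) {
      e2 <- enc
      e2$par[[nm]][ii] <- e2$par[[nm]][ii] + eps
      lp <- lossfun(e2, x)
      e2$par[[nm]][ii] <- e2$par[[nm]][ii] - 2 * eps
      lm <- lossfun(e2, x)
      fd <- (lp - lm) / (2 * eps)
      an <- bk$grads[[nm]][ii]
      # absolute floor absorbs finite-difference roundoff on tiny gradients
      expect_lt(abs(fd - an), 1e-7 + 1e-3 * abs(an))
    }
  }
  # input gradient (the path that reaches the DAMix mask)
  for (ii in sample(length(x), 4L)) {
    x2 <- x; x2[ii] <- x2[ii] + eps; lp <- lossfun(enc, x2)
    x2[ii] <- x2[ii] - 2 * eps; lm <- lossfun(enc, x2)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - bk$gx[ii]), 1e-7 + 1e-3 * abs(bk$gx[ii]))
  }
})
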