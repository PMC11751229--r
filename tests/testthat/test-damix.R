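# DAMix block: mixing-ratio sampling, region tokens, routed attention vs a
# dense oracle, lambda embedding, mask generation, efficient mixup.

test_that("mixing ratios follow Beta(alpha, alpha) and are reproducible", {
  set.seed(1)
  draws <- sample_lambda(1, 10000L)
  # Beta(1,1) = Uniform(0,1): mean 1/2, sd 1/sqrt(12)
  se <- 1 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  expect_true(all(draws > 0 & draws < 1))
  set.seed(2)
  tight <- sample_lambda(100, 10000L)
  expect_lt(var(tight), var(draws))
  set.seed(3); a <- sample_lambda(0.5, 5L)
  set.seed(3); b <- sample_lambda(0.5, 5L)
  expect_identical(a, b)
  expect_error(sample_lambda(0), "alpha")
  expect_error(sample_lambda(-1), "alpha")
})

test_that("regionize produces S^2 lossless tokens", {
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  g <- regionize(f, 2L)
  expect_equal(dim(g$tokens), c(4L, 4L, 3L))   # 4 tokens x 4 positions x C
  expect_identical(deregionize(g), f)
  g1 <- regionize(f, 1L)
  expect_equal(dim(g1$tokens)[1], 1L)
  expect_identical(deregionize(g1), f)
  expect_error(regionize(f, 3L), "divide")
})

test_that("routed attention with k = S^2 equals dense attention", {
  set.seed(21)
  C <- 4L
  par <- list(Wq = matrix(rnorm(C * C, sd = 0.5), C, C),
              Wk = matrix(rnorm(C * C, sd = 0.5), C, C),
              Wv = matrix(rnorm(C * C, sd = 0.5), C, C))
  for (i in 1:5) {
    f <- array(rnorm(8 * 8 * C), c(8, 8, C))
    X <- matrix(f, 64, C)
    want <- X + dense_attention_oracle(X, par$Wq, par$Wk, par$Wv)
    got <- dynamic_attention(f, par, S = 2L, k = 4L)
    expect_lt(max(abs(matrix(got, 64, C) - want)), 1e-5)
    got1 <- dynamic_attention(f, par, S = 1L, k = 1L)
    expect_lt(max(abs(matrix(got1, 64, C) - want)), 1e-5)
  }
  # zero projections: attention contributes nothing, residual passes through
  zpar <- list(Wq = matrix(0, C, C), Wk = matrix(0, C, C), Wv = matrix(0, C, C))
  f <- array(rnorm(8 * 8 * C), c(8, 8, C))
  expect_equal(dynamic_attention(f, zpar, S = 2L, k = 2L), f)
  expect_error(dynamic_attention(f, par, S = 2L, k = 5L), "k")
})

test_that("routed attention with k < S^2 restricts keys to the top-k regions", {
  set.seed(33)
  C <- 3L
  par <- list(Wq = diag(C), Wk = diag(C), Wv = diag(C))
  f <- array(rnorm(4 * 4 * C), c(4, 4, C))
  got <- dynamic_attention(f, par, S = 2L, k = 1L)
  # with k = 1 every query region attends within one region only; output
  # must differ from dense attention for generic inputs
  X <- matrix(f, 16, C)
  dense <- X + dense_attention_oracle(X, par$Wq, par$Wk, par$Wv)
  expect_gt(max(abs(matrix(got, 16, C) - dense)), 1e-8)
})

test_that("lambda embedding reaches the output exactly when weighted", {
  set.seed(4)
  C <- 5L
  blk <- list(W = matrix(rnorm(C * (C + 1), sd = 0.3), C, C + 1),
              b = rnorm(C))
  f <- array(rnorm(4 * 4 * C), c(4, 4, C))
  lo <- embed_lambda(f, 0.1, blk)
  hi <- embed_lambda(f, 0.9, blk)
  expect_equal(dim(lo), dim(f))
  expect_gt(max(abs(lo - hi)), 0)
  blk0 <- blk
  blk0$W[, C + 1] <- 0  # zero the lambda-channel weights
  expect_equal(embed_lambda(f, 0.1, blk0), embed_lambda(f, 0.9, blk0))
})

test_that("generated masks are strictly inside (0,1) and asymmetric in the pair", {
  set.seed(6)
  C <- 6L
  dmx <- spemix:::damix_init(C, seed = 2L)
  z1 <- array(rnorm(4 * 4 * C), c(4, 4, C))
  z2 <- array(rnorm(4 * 4 * C), c(4, 4, C))
  M <- generate_mask(z1, z2, 0.4, dmx, out_size = c(32L, 32L))
  expect_equal(dim(M), c(32L, 32L))
  expect_true(all(M > 0 & M < 1))
  M2 <- generate_mask(z2, z1, 0.4, dmx, out_size = c(32L, 32L))
  expect_gt(max(abs(M - M2)), 1e-8)
  expect_error(generate_mask(z1, array(0, c(2, 2, C)), 0.4, dmx), "identical")
  # cross-attention rows are a proper softmax
  fwd <- spemix:::maskgen_fwd(matrix(z1, 16, C), matrix(z2, 16, C), 0.4,
                              dmx, 4L, 4L, c(8L, 8L))
  expect_lt(max(abs(rowSums(fwd$cache$P2) - 1)), 1e-6)
})

test_that("efficient mixup is an exact pixelwise convex combination", {
  set.seed(9)
  u1 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  u2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_identical(efficient_mixup(u1, u2, matrix(1, 8, 8)), u1)
  expect_identical(efficient_mixup(u1, u2, matrix(0, 8, 8)), u2)
  expect_equal(efficient_mixup(u1, u2, matrix(0.5, 8, 8)), (u1 + u2) / 2)
  for (i in 1:20) {
    M <- matrix(runif(64), 8, 8)
    um <- efficient_mixup(u1, u2, M)
    expect_true(all(um >= pmin(u1, u2) - 1e-12 & um <= pmax(u1, u2) + 1e-12))
  }
  expect_error(efficient_mixup(u1, u2, matrix(1.5, 8, 8)), "mask")
  expect_error(efficient_mixup(u1, u2[, , 1:2], matrix(1, 8, 8)), "identical")
})

test_that("DAMix parameter gradients match finite differences", {
  set.seed(7)
  ns <- asNamespace("spemix")
  C <- 5L
  dmx <- ns$damix_init(C, seed = 5L)
  tap1 <- array(rnorm(C * 4 * 4 * 2), c(C, 4, 4, 2))
  tap2 <- array(rnorm(C * 4 * 4 * 2), c(C, 4, 4, 2))
  R <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  lossfun <- function(par) {
    sum(ns$damix_forward(par, tap1, tap2, 0.37, c(16L, 16L), 2L, 4L)$M * R)
  }
  fw <- ns$damix_forward(dmx, tap1, tap2, 0.37, c(16L, 16L), 2L, 4L)
  gd <- ns$damix_backward(dmx, fw, R)
  flat <- ns$dmx_flat(dmx)
  eps <- 1e-6
  for (nm in c("Wq", "Wk", "Wv", "qb.W", "kb.W", "vb.W", "proj.w")) {
    for (ii in sample(length(flat[[nm]]), 2L)) {
      f2 <- flat
      f2[[nm]][ii] <- f2[[nm]][ii] + eps
      lp <- lossfun(ns$dmx_unflat(f2, dmx))
      f2[[nm]][ii] <- f2[[nm]][ii] - 2 * eps
      lm <- lossfun(ns$dmx_unflat(f2, dmx))
      fd <- (lp - lm) / (2 * eps)
      an <- gd[[nm]][ii]
      expect_lt(abs(fd - an) / max(1e-5, abs(fd) + abs(an)), 1e-3)
    }
  }
})
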