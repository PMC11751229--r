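# Loss terms: closed-form values, additivity, hard-negative selection.

test_that("soft cross-entropy has its closed-form values", {
  expect_lt(soft_cross_entropy(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  expect_equal(soft_cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(soft_cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), log(2))
  # equals the entropy of the target at pred = target
  t0 <- c(0.2, 0.3, 0.5)
  expect_equal(soft_cross_entropy(t0, t0), -sum(t0 * log(t0)))
  expect_error(soft_cross_entropy(c(0.7, 0.7), c(0.5, 0.5)), "probability")
  expect_error(soft_cross_entropy(c(1, 0), c(0.9, 0.2)), "probability")
})

test_that("generation loss endpoints and mixtures are exact", {
  p1 <- c(1, 0); p2 <- c(0, 1); pm <- c(0.5, 0.5)
  expect_equal(gen_loss(p1, p2, pm, 1), soft_cross_entropy(p1, pm))
  expect_equal(gen_loss(p1, p2, pm, 0.5), log(2))
  # minimum given targets: p1 = p2 = p_mix gives the entropy of p1
  t0 <- c(0.3, 0.7)
  expect_equal(gen_loss(t0, t0, t0, 0.4), -sum(t0 * log(t0)))
})

test_that("DAMix loss adds the labeled cross-entropy", {
  expect_equal(damix_loss(0, rep(0.25, 4), 0L), log(4))
  perfect <- c(1 - 3e-9, 1e-9, 1e-9, 1e-9)
  expect_lt(abs(damix_loss(0.7, perfect, 0L) - 0.7), 1e-6)
  set.seed(1)
  for (i in 1:10) {
    gen <- runif(1, 0, 2)
    pred <- runif_simplex(4)
    y <- sample(0:3, 1)
    expect_equal(damix_loss(gen, pred, y) - gen,
                 soft_cross_entropy(as.numeric(0:3 == y), pred),
                 tolerance = 1e-12)
  }
  expect_error(damix_loss(0, rep(0.25, 4), 4L), "labels")
})

test_that("multi-binary loss penalizes the true head and the hardest negative", {
  Q <- cbind(c(0.9, 0.3), 1 - c(0.9, 0.3))
  expect_equal(multi_binary_loss(Q, 0L), -log(0.9) - log(0.7))
  # perfect one-vs-rest heads: loss ~ 0
  Qp <- cbind(c(1, 0, 0, 0), c(0, 1, 1, 1))
  expect_lt(multi_binary_loss(Qp, 0L), 1e-6)
  # brute-force oracle: min over k != y of log(1 - q_k)
  set.seed(33)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    q <- runif(K, 0.05, 0.95)
    y <- sample(0:(K - 1), 1)
    oracle <- -log(q[y + 1]) - min(log(1 - q[setdiff(seq_len(K), y + 1)]))
    expect_equal(multi_binary_loss(cbind(q, 1 - q), y), oracle,
                 tolerance = 1e-12)
  }
  expect_error(multi_binary_loss(cbind(0.5, 0.5), 0L), "K >= 2")
})

test_that("SP loss is the sum of its parts", {
  expect_equal(sp_loss(rep(0.25, 4), 0L, cbind(c(1, 0, 0, 0), c(0, 1, 1, 1)), 0L),
               log(4), tolerance = 1e-6)
  set.seed(4)
  pred <- runif_simplex(4)
  q <- runif(4, 0.1, 0.9)
  got <- sp_loss(pred, 1L, cbind(q, 1 - q), 1L)
  expect_equal(got,
               soft_cross_entropy(c(0, 1, 0, 0), pred) +
                 multi_binary_loss(cbind(q, 1 - q), 1L))
})

test_that("open-set loss uses hard argmax pseudo-labels", {
  sp1 <- c(0.9, 0.05, 0.02, 0.02, 0.01)   # y_sp = 0
  sp2 <- c(0.1, 0.1, 0.1, 0.1, 0.6)       # y_sp = 4
  o_uniform <- rep(0.2, 5)
  for (lam in c(0.2, 0.5, 0.9)) {
    expect_equal(open_set_loss(sp1, sp2, o_uniform, lam), log(5))
  }
  o_hit <- c(1 - 4e-9, rep(1e-9, 4))
  expect_lt(open_set_loss(sp1, sp2, o_hit, 1), 1e-6)
  # coincident targets reduce to a single cross-entropy
  set.seed(8)
  o <- runif_simplex(5)
  expect_equal(open_set_loss(sp1, sp1, o, 0.5),
               soft_cross_entropy(c(1, 0, 0, 0, 0), o))
})

test_that("total loss is the unweighted sum and all terms are nonnegative", {
  expect_equal(total_loss(list(damix = 1, sp = 2, op = 3)), 6)
  expect_equal(total_loss(list(damix = 0, sp = 0, op = 0)), 0)
  set.seed(12)
  for (i in 1:20) {
    p1 <- runif_simplex(4); p2 <- runif_simplex(4); pm <- runif_simplex(4)
    lam <- runif(1)
    q <- runif(4, 0.05, 0.95)
    y <- sample(0:3, 1)
    lg <- gen_loss(p1, p2, pm, lam)
    ld <- damix_loss(lg, runif_simplex(4), y)
    ls <- sp_loss(runif_simplex(4), y, cbind(q, 1 - q), y)
    lo <- open_set_loss(runif_simplex(5), runif_simplex(5), runif_simplex(5), lam)
    expect_true(all(c(lg, ld, ls, lo) >= 0))
    expect_equal(total_loss(list(damix = ld, sp = ls, op = lo)), ld + ls + lo)
  }
})
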