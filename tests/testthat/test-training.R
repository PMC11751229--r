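# Training loop mechanics: EMA, schedule, step determinism, gradient
# isolation, loss decomposition, learnability smoke test.

test_that("EMA update follows its closed form", {
  expect_equal(ema_update(2, 1, 0.5), 1.5)
  expect_equal(ema_update(2, 1, 1), 2)
  t0 <- list(a = matrix(2, 2, 2), b = list(c = rep(4, 3)))
  s <- list(a = matrix(1, 2, 2), b = list(c = rep(0, 3)))
  th <- t0
  for (i in 1:10) th <- ema_update(th, s, 0.999)
  m10 <- 0.999^10
  expect_lt(max(abs(th$a - (m10 * 2 + (1 - m10) * 1))), 1e-6)
  expect_lt(max(abs(th$b$c - (m10 * 4))), 1e-6)
  # 100-step closed form
  th <- t0
  for (i in 1:100) th <- ema_update(th, s, 0.99)
  expect_lt(max(abs(th$a - (0.99^100 * 2 + (1 - 0.99^100)))), 1e-6)
  expect_error(ema_update(list(a = 1:2), list(a = 1:3), 0.5), "match")
})

test_that("cosine schedule hits its endpoints without warm-up", {
  expect_equal(cosine_lr(0, 100, 1e-4), 1e-4)
  expect_equal(cosine_lr(50, 100, 1e-4), 5e-5)
  expect_equal(cosine_lr(100, 100, 1e-4), 0)
  lrs <- sapply(0:100, cosine_lr, total_steps = 100, base_lr = 1e-4)
  expect_true(all(diff(lrs) <= 1e-12))
  expect_warning(got <- cosine_lr(120, 100, 1e-4), "clamp")
  expect_equal(got, 0)
})

test_that("one training step is bit-reproducible and keeps the teacher body frozen", {
  ds <- tiny_dataset()
  f0 <- spemix(ds, train = train_config(epochs = 0L), encoder = tiny_encoder(),
               seed = 3L)
  st <- f0$state
  st$total_steps <- 100L
  lb <- list(images = ds$labeled$images, labels = ds$labeled$labels)
  ub <- ds$unlabeled$images
  set.seed(42); r1 <- train_step(st, lb, ub)
  set.seed(42); r2 <- train_step(st, lb, ub)
  expect_identical(r1$terms, r2$terms)
  expect_identical(r1$state$student$enc$par, r2$state$student$enc$par)
  # all loss terms finite and decomposition holds
  expect_true(all(is.finite(unlist(r1$terms))))
  expect_equal(r1$terms$total, r1$terms$damix + r1$terms$sp + r1$terms$op)
  # teacher body receives no gradient: with m = 1 the teacher is bit-identical
  st1 <- st
  st1$train_cfg$ema_momentum <- 1
  set.seed(7); r3 <- train_step(st1, lb, ub)
  expect_identical(r3$state$teacher$enc$par, st1$teacher$enc$par)
  expect_identical(r3$state$teacher$close, st1$teacher$close)
  # no optimizer state exists for teacher parameters
  expect_false(any(grepl("teacher", names(st$opt$m))))
  # the student and the DAMix parameters did move (nonzero gradients)
  expect_gt(max(abs(r3$state$damix$Wq - st1$damix$Wq)), 0)
  expect_gt(max(abs(r3$state$damix$proj$w - st1$damix$proj$w)), 0)
  expect_gt(max(abs(r3$state$student$heads$close$W - st1$student$heads$close$W)), 0)
})

test_that("fits are deterministic and epochs = 0 returns an initialized state", {
  ds <- tiny_dataset()
  f0 <- spemix(ds, train = train_config(epochs = 0L), encoder = tiny_encoder(),
               seed = 1L)
  expect_equal(nrow(f0$history), 0L)
  expect_equal(f0$state$step, 0L)
  fa <- spemix(ds, train = desk_train_config(epochs = 2L),
               encoder = tiny_encoder(), seed = 5L)
  fb <- spemix(ds, train = desk_train_config(epochs = 2L),
               encoder = tiny_encoder(), seed = 5L)
  expect_identical(fa$history$val_acc, fb$history$val_acc)
  expect_identical(fa$state$student$enc$par, fb$state$student$enc$par)
  expect_equal(fa$history$total, fa$history$damix + fa$history$sp + fa$history$op)
})

test_that("degenerate inputs degrade as specified", {
  ds <- tiny_dataset()
  empty_unl <- ds
  empty_unl$unlabeled <- list(images = array(0, c(32, 32, 0)),
                              hidden_labels = integer(0))
  expect_warning(f <- spemix(empty_unl, train = train_config(epochs = 1L),
                             encoder = tiny_encoder(), seed = 1L),
                 "supervised")
  expect_equal(f$loss_mode, "supervised")
  empty_lab <- ds
  empty_lab$labeled <- list(images = array(0, c(32, 32, 0)), labels = integer(0))
  expect_error(spemix(empty_lab, encoder = tiny_encoder()), "labeled")
})

test_that("labeled loss decreases over 50 steps on the default conditions", {
  ds <- get_default_ds()
  deltas <- sapply(1:3, function(seed) {
    f0 <- spemix(ds, train = desk_train_config(epochs = 0L), seed = seed)
    st <- f0$state
    st$total_steps <- 50L
    first <- NA_real_; last <- NA_real_
    set.seed(seed * 100)
    for (i in 1:50) {
      li <- sample.int(100, 64)
      ui <- sample.int(2000, 64)
      r <- train_step(st, list(images = ds$labeled$images[, , li],
                               labels = ds$labeled$labels[li]),
                      ds$unlabeled$images[, , ui])
      st <- r$state
      if (i == 1) first <- r$terms$labeled
      if (i == 50) last <- r$terms$labeled
    }
    first - last
  })
  expect_gt(median(deltas), 0)
})
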