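# Metrics: confusion matrix, ROC/AUC against a pairwise oracle, report.

test_that("confusion matrix is row-normalized with hand-checked entries", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(cm, diag(3))
  cm2 <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(cm2, rbind(c(0.5, 0.5), c(0, 1)))
  set.seed(1)
  yt <- sample(0:3, 200, replace = TRUE)
  yp <- sample(0:3, 200, replace = TRUE)
  expect_equal(rowSums(confusion_matrix(yt, yp, 4)), rep(1, 4))
  expect_warning(cm3 <- confusion_matrix(c(0, 0), c(0, 1), 3), "no samples")
  expect_true(all(is.nan(cm3[3, ])))
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "labels")
})

test_that("roc_auc equals the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5)), 0.5)
  set.seed(77)
  for (i in 1:50) {
    n <- 200
    labels <- rep(0:1, each = n / 2)
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    if (runif(1) < 0.3) scores <- round(scores, 1)  # force ties sometimes
    expect_lt(abs(roc_auc(scores, labels) - pairwise_auc_oracle(scores, labels)),
              1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("roc curves contain both endpoints and an external check agrees", {
  set.seed(3)
  labels <- rep(0:1, each = 50)
  scores <- rnorm(100) + labels
  pts <- roc_points(scores, labels)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  if (requireNamespace("pROC", quietly = TRUE)) {
    ext <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ext, tolerance = 1e-10)
  }
})

test_that("evaluate produces a consistent report and JSON export round-trips", {
  ds <- tiny_dataset()
  f <- spemix(ds, train = desk_train_config(epochs = 1L),
              encoder = tiny_encoder(), seed = 2L)
  m <- evaluate(f, ds)
  expect_s3_class(m, "spemix_metrics")
  expect_equal(rowSums(m$confusion), rep(1, 4), ignore_attr = TRUE)
  # overall accuracy equals the label-frequency-weighted diagonal
  freq <- as.vector(table(factor(ds$test$labels, levels = 0:3))) /
    length(ds$test$labels)
  expect_equal(m$overall_accuracy, sum(freq * m$per_class_accuracy),
               tolerance = 1e-12)
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_equal(m$n_parameters, count_parameters(f))
  expect_false(is.na(m$ood_auroc))
  out <- tempfile("metrics")
  evaluate(f, ds, export_dir = out)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    j <- jsonlite::read_json(file.path(out, "metrics.json"), simplifyVector = TRUE)
    expect_equal(j$overall_accuracy, m$overall_accuracy)
    expect_equal(unname(unlist(j$auc)), unname(m$auc))
  }
  expect_true(file.exists(file.path(out, "confusion.csv")))
  expect_true(file.exists(file.path(out, "roc_A2C.csv")))
  unlink(out, recursive = TRUE)
})

test_that("prediction uses the close-set argmax with lowest-index ties", {
  ds <- tiny_dataset()
  f <- spemix(ds, train = train_config(epochs = 0L), encoder = tiny_encoder(),
              seed = 1L)
  # zero the close head: uniform P everywhere, predictions fall to class 0
  f$state$student$heads$close$W[] <- 0
  f$state$student$heads$close$b[] <- 0
  pr <- predict(f, ds$test$images, type = "all")
  expect_true(all(pr$class == 0L))
  expect_equal(rowSums(pr$Dp), rep(1, length(ds$test$labels)), tolerance = 1e-9)
  # batch-size invariance
  p1 <- predict(f, ds$test$images[, , 1, drop = FALSE], type = "prob")
  pb <- predict(f, ds$test$images, type = "prob")
  expect_equal(p1[1, ], pb[1, ], tolerance = 1e-9)
})
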