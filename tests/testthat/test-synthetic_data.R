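# Synthetic sector-fan generator: determinism, geometry, bookkeeping, I/O.

test_that("view images are deterministic, class-distinct, fan-masked", {
  spec <- synth_spec(speckle_strength = 0)
  set.seed(3); a <- make_view_image(0, spec)
  set.seed(3); b <- make_view_image(0, spec)
  expect_identical(a, b)
  set.seed(3); psax <- make_view_image(3, spec)
  expect_gt(mean(abs(a - psax)), 0)
  geo <- spemix:::sector_geometry(spec$image_size)
  for (k in 0:5) {
    set.seed(k)
    im <- make_view_image(k, spec)
    expect_true(all(im[!geo$mask] == 0))
    expect_true(all(im >= 0 & im <= 1))
  }
  expect_error(make_view_image(6, spec), "class_id")
  expect_error(make_view_image(-1, spec), "class_id")
})

test_that("speckle is multiplicative and respects the fan mask", {
  spec0 <- synth_spec(speckle_strength = 0)
  spec1 <- synth_spec(speckle_strength = 0.4)
  set.seed(11); clean <- make_view_image(2, spec0)
  set.seed(11); noisy <- make_view_image(2, spec1)
  expect_gt(sd(noisy - clean), 0)
  # zero pixels stay exactly zero under multiplicative noise
  expect_true(all(noisy[clean == 0] == 0))
})

test_that("dataset bookkeeping: sizes, balance, OOD rounding, determinism", {
  spec <- synth_spec(n_labeled_per_class = 10L, n_unlabeled = 100L,
                     ood_fraction = 0.3, n_test_per_class = 5L, seed = 2L)
  ds <- make_dataset(spec)
  expect_equal(dim(ds$labeled$images)[3], 40L)
  expect_equal(as.vector(table(ds$labeled$labels)), rep(10L, 4))
  expect_equal(sum(ds$unlabeled$hidden_labels >= 4L), 30L)
  expect_true(all(ds$labeled$labels < 4L))
  expect_true(all(ds$unlabeled$hidden_labels < 6L))
  ds2 <- make_dataset(spec)
  expect_identical(ds$unlabeled$images, ds2$unlabeled$images)
  expect_identical(ds$labeled$images, ds2$labeled$images)
  # half-away-from-zero rounding: 10 * 0.25 = 2.5 -> 3
  s3 <- synth_spec(n_unlabeled = 10L, ood_fraction = 0.25,
                   n_labeled_per_class = 2L, n_test_per_class = 2L)
  expect_equal(sum(make_dataset(s3)$unlabeled$hidden_labels >= 4L), 3L)
  expect_error(make_dataset(synth_spec(n_id_classes = 0L)), "0 in-distribution")
})

test_that("noise-free classes are nearest-centroid separable and OOD means are distinct", {
  spec <- synth_spec(speckle_strength = 0, n_labeled_per_class = 25L,
                     n_test_per_class = 50L, n_unlabeled = 120L, seed = 9L)
  ds <- make_dataset(spec)
  tr <- matrix(ds$labeled$images, 32 * 32)
  cent <- sapply(0:3, function(k) rowMeans(tr[, ds$labeled$labels == k]))
  te <- matrix(ds$test$images, 32 * 32)
  pred <- apply(te, 2, function(v) which.min(colSums((cent - v)^2)) - 1L)
  expect_equal(mean(pred == ds$test$labels), 1.0)
  # every OOD class mean differs from every ID class mean
  for (k in 4:5) {
    mu_ood <- rowMeans(matrix(ds$unlabeled$images[, , ds$unlabeled$hidden_labels == k],
                              32 * 32))
    for (j in 0:3) expect_gt(sqrt(sum((mu_ood - cent[, j + 1])^2)), 0)
  }
})

test_that("image-folder round trip preserves pixels and layout", {
  ds <- make_dataset(synth_spec(n_labeled_per_class = 2L, n_unlabeled = 6L,
                                n_test_per_class = 2L, seed = 4L))
  root <- tempfile("imgfolder")
  man <- write_image_folder(ds, root)
  n_total <- 8L + 6L + 8L
  expect_equal(nrow(man), n_total)
  expect_equal(length(list.files(root, pattern = "\\.png$", recursive = TRUE)),
               n_total)
  # unlabeled folder is flat
  expect_equal(length(list.dirs(file.path(root, "unlabeled"),
                                recursive = FALSE)), 0L)
  back <- read_image_folder(root)
  expect_equal(dim(back$labeled$images), dim(ds$labeled$images))
  # 8-bit quantization bound; ordering of files matches writing order
  expect_lt(max(abs(back$unlabeled$images - ds$unlabeled$images)), 1 / 255 + 1e-9)
  expect_equal(back$unlabeled$hidden_labels, ds$unlabeled$hidden_labels)
  expect_equal(sort(back$class_names), sort(ds$class_names))
  unlink(root, recursive = TRUE)
})
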