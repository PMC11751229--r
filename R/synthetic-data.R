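# Synthetic echocardiogram-like image generator. Images mimic the gross
# statistical structure of B-mode echo stills: an apex-up sector fan on a
# black background, bright myocardial walls, dark blood-filled chambers,
# multiplicative speckle, and per-image pose jitter. In-distribution
# classes emulate the four standard views by chamber count/arrangement;
# out-of-distribution classes use geometry disjoint from all four.

#' Synthetic dataset specification
#'
#' @param image_size pixels per side (>= 16; 32 is the desk-scale default,
#'   112 mirrors clinical-resolution inputs).
#' @param n_id_classes in-distribution view classes (4: A2C, A4C, PLAX,
#'   PSAX look-alikes).
#' @param n_ood_classes out-of-distribution view classes appearing only in
#'   the unlabeled pool.
#' @param n_labeled_per_class labeled images per in-distribution class.
#' @param n_unlabeled unlabeled pool size.
#' @param ood_fraction fraction of the unlabeled pool drawn from
#'   out-of-distribution classes, in [0, 1].
#' @param n_test_per_class test images per in-distribution class.
#' @param speckle_strength multiplicative speckle level `s` in
#'   `x * (1 + s * g)`, `g` standard normal per pixel.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(image_size = 32L, n_id_classes = 4L, n_ood_classes = 2L,
                       n_labeled_per_class = 25L, n_unlabeled = 2000L,
                       ood_fraction = 0.3, n_test_per_class = 100L,
                       speckle_strength = 0.4, seed = 1L) {
  stopifnot(image_size >= 16L, ood_fraction >= 0, ood_fraction <= 1,
            n_id_classes >= 0L, n_id_classes <= 4L, n_ood_classes >= 0L,
            n_labeled_per_class >= 0L, n_unlabeled >= 0L,
            n_test_per_class >= 0L, speckle_strength >= 0)
  id_names <- c("A2C", "A4C", "PLAX", "PSAX", paste0("ID", seq_len(16)))
  structure(list(image_size = as.integer(image_size),
                 n_id_classes = as.integer(n_id_classes),
                 n_ood_classes = as.integer(n_ood_classes),
                 n_labeled_per_class = as.integer(n_labeled_per_class),
                 n_unlabeled = as.integer(n_unlabeled),
                 ood_fraction = ood_fraction,
                 n_test_per_class = as.integer(n_test_per_class),
                 speckle_strength = speckle_strength,
                 seed = as.integer(seed),
                 class_names = c(head(id_names, n_id_classes),
                                 paste0("OOD", seq_len(n_ood_classes)))),
            class = "synth_spec")
}

# apex-up sector fan mask and polar coordinates on the unit square
sector_geometry <- function(n) {
  x <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)   # column coord
  y <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n)  # row coord
  dx <- x - 0.5
  dy <- y - 0.05
  r <- sqrt(dx * dx + dy * dy)
  ang <- atan2(dx, dy)  # 0 = straight down from the apex
  mask <- (abs(ang) <= 0.62) & (r >= 0.08) & (r <= 0.92)
  list(x = x, y = y, r = r, mask = mask)
}

# ellipse membership in a rotated/scaled/shifted local frame
in_ellipse <- function(u, v, cu, cv, au, av, rot = 0) {
  du <- u - cu; dv <- v - cv
  if (rot != 0) {
    ru <- cos(rot) * du + sin(rot) * dv
    rv <- -sin(rot) * du + cos(rot) * dv
    du <- ru; dv <- rv
  }
  (du / au)^2 + (dv / av)^2 < 1
}

#' Generate one synthetic view image
#'
#' Draws a single grayscale sector-fan image of the given class using the
#' current RNG stream (wrap in `set.seed()` for reproducibility). Classes
#' `0..n_id_classes-1` are the in-distribution views (single large cavity
#' ~ A2C; 2x2 cavity grid ~ A4C; oblique cavity pair ~ PLAX; bright ring
#' ~ PSAX); classes `>= n_id_classes` are out-of-distribution geometries
#' (diagonal cavity triplet; random blob field). Pose jitter (shift,
#' scale, rotation) and multiplicative speckle are applied per image;
#' pixels outside the sector fan are exactly 0.
#'
#' @param class_id 0-based class index,
#'   `< n_id_classes + n_ood_classes`.
#' @param spec a [synth_spec()].
#' @return `image_size x image_size` matrix with values in [0, 1].
#' @export
make_view_image <- function(class_id, spec) {
  n_classes <- spec$n_id_classes + spec$n_ood_classes
  if (class_id < 0 || class_id >= n_classes) {
    stop(sprintf("class_id must lie in 0..%d", n_classes - 1L))
  }
  n <- spec$image_size
  geo <- sector_geometry(n)
  # pose jitter: shift of the structure centre, isotropic scale, rotation.
  # Amplitudes are capped so that classes stay separable in pixel space
  # (a nearest-centroid classifier on noise-free images must be exact).
  cx <- 0.5 + runif(1, -0.04, 0.04)
  cy <- 0.55 + runif(1, -0.04, 0.04)
  sc <- runif(1, 0.92, 1.08)
  th <- runif(1, -0.05, 0.05)
  du <- (geo$x - cx) / sc
  dv <- (geo$y - cy) / sc
  u <- cos(th) * du + sin(th) * dv
  v <- -sin(th) * du + cos(th) * dv
  wall <- 0.8 - 0.2 * geo$r  # mild depth attenuation
  cav <- matrix(FALSE, n, n)
  bright <- matrix(FALSE, n, n)
  is_ood <- class_id >= spec$n_id_classes
  if (is_ood && class_id == spec$n_id_classes) {  # OOD: diagonal cavity triplet
    cav <- in_ellipse(u, v, -0.15, -0.15, 0.06, 0.06) |
      in_ellipse(u, v, 0, 0, 0.06, 0.06) |
      in_ellipse(u, v, 0.15, 0.15, 0.06, 0.06)
  } else if (is_ood) {             # OOD: random blob field
    for (j in 1:6) {
      cc <- runif(2, -0.2, 0.2)
      rad <- runif(2, 0.03, 0.07)
      cav <- cav | in_ellipse(u, v, cc[1], cc[2], rad[1], rad[2])
    }
  } else if (class_id == 0L) {     # A2C-like: one large central cavity
    cav <- in_ellipse(u, v, 0, 0, 0.16, 0.26)
  } else if (class_id == 1L) {     # A4C-like: four cavities in a 2x2 grid
    cav <- in_ellipse(u, v, -0.12, -0.12, 0.07, 0.08) |
      in_ellipse(u, v, 0.12, -0.12, 0.07, 0.08) |
      in_ellipse(u, v, -0.12, 0.12, 0.07, 0.08) |
      in_ellipse(u, v, 0.12, 0.12, 0.07, 0.08)
  } else if (class_id == 2L) {     # PLAX-like: oblique cavity pair
    cav <- in_ellipse(u, v, -0.13, -0.09, 0.14, 0.055, rot = 0.7) |
      in_ellipse(u, v, 0.14, 0.10, 0.11, 0.05, rot = 0.7)
  } else {                         # PSAX-like: bright ring, dark core
    rr <- sqrt(u * u + v * v)
    cav <- rr < 0.12
    bright <- rr >= 0.12 & rr < 0.22
  }
  img <- wall
  img[cav] <- 0.08
  img[bright] <- 0.95
  if (spec$speckle_strength > 0) {
    g <- matrix(rnorm(n * n), n, n)
    img <- img * (1 + spec$speckle_strength * g)
  }
  img[!geo$mask] <- 0
  pmin(pmax(img, 0), 1)
}

round_half_away <- function(x) floor(x + 0.5)

#' Generate a full synthetic open-set dataset
#'
#' Builds balanced labeled and test splits over the in-distribution
#' classes and an unlabeled pool in which
#' `round(ood_fraction * n_unlabeled)` images (half-away-from-zero
#' rounding) come from out-of-distribution classes; the remainder is
#' filled with in-distribution images cycling uniformly over classes.
#' Hidden unlabeled ground truth (indices `>= n_id_classes` marking OOD)
#' is kept for evaluation only and never used in training.
#'
#' @param spec a [synth_spec()].
#' @return object of class `synth_dataset`: lists `labeled(images,
#'   labels)`, `unlabeled(images, hidden_labels)`, `test(images, labels)`
#'   plus `class_names`. Images are `H x W x B` arrays; labels 0-based.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  K <- spec$n_id_classes
  if (K == 0L) stop("cannot build a dataset with 0 in-distribution classes")
  n <- spec$image_size
  gen_split <- function(class_ids) {
    B <- length(class_ids)
    imgs <- array(0, c(n, n, B))
    for (i in seq_len(B)) imgs[, , i] <- make_view_image(class_ids[i], spec)
    imgs
  }
  with_seed(spec$seed, {
    lab_cls <- rep(0:(K - 1L), each = spec$n_labeled_per_class)
    test_cls <- rep(0:(K - 1L), each = spec$n_test_per_class)
    n_ood <- as.integer(round_half_away(spec$ood_fraction * spec$n_unlabeled))
    if (spec$n_ood_classes == 0L) n_ood <- 0L
    n_id <- spec$n_unlabeled - n_ood
    u_cls <- c(rep_len(0:(K - 1L), n_id),
               if (n_ood > 0L) rep_len(K:(K + spec$n_ood_classes - 1L), n_ood))
    u_cls <- if (length(u_cls)) sample(u_cls) else integer(0)
    structure(list(
      labeled = list(images = gen_split(lab_cls), labels = lab_cls),
      unlabeled = list(images = gen_split(u_cls), hidden_labels = u_cls),
      test = list(images = gen_split(test_cls), labels = test_cls),
      class_names = spec$class_names[seq_len(K)],
      spec = spec), class = "synth_dataset")
  })
}

#' Write a dataset as an image folder
#'
#' Layout: `labeled/<class_name>/*.png`, `unlabeled/*.png` (flat — no
#' class subdirectories), `test/<class_name>/*.png`, all 8-bit grayscale
#' PNG, plus a `manifest.csv` with columns
#' `file,split,label,hidden_label`.
#'
#' @param dataset a [make_dataset()] result.
#' @param root output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_image_folder <- function(dataset, root) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop(sprintf("cannot create directory '%s'", root))
  rows <- list()
  emit <- function(img, rel) {
    png::writePNG(img, file.path(root, rel))
    rel
  }
  for (k in seq_along(dataset$class_names)) {
    cn <- dataset$class_names[k]
    dir.create(file.path(root, "labeled", cn), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "test", cn), recursive = TRUE, showWarnings = FALSE)
  }
  dir.create(file.path(root, "unlabeled"), recursive = TRUE, showWarnings = FALSE)
  lab <- dataset$labeled
  for (i in seq_along(lab$labels)) {
    cn <- dataset$class_names[lab$labels[i] + 1L]
    rel <- emit(lab$images[, , i], file.path("labeled", cn, sprintf("l%04d.png", i)))
    rows[[length(rows) + 1L]] <- data.frame(file = rel, split = "labeled",
                                            label = lab$labels[i],
                                            hidden_label = lab$labels[i])
  }
  unl <- dataset$unlabeled
  nu <- dim(unl$images)[3]
  for (i in seq_len(nu)) {
    rel <- emit(unl$images[, , i], file.path("unlabeled", sprintf("u%05d.png", i)))
    rows[[length(rows) + 1L]] <- data.frame(file = rel, split = "unlabeled",
                                            label = NA_integer_,
                                            hidden_label = unl$hidden_labels[i])
  }
  tst <- dataset$test
  for (i in seq_along(tst$labels)) {
    cn <- dataset$class_names[tst$labels[i] + 1L]
    rel <- emit(tst$images[, , i], file.path("test", cn, sprintf("t%04d.png", i)))
    rows[[length(rows) + 1L]] <- data.frame(file = rel, split = "test",
                                            label = tst$labels[i],
                                            hidden_label = tst$labels[i])
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image-folder dataset
#'
#' Reads a directory in the [write_image_folder()] layout back into a
#' `synth_dataset`-shaped list. Hidden unlabeled labels are restored from
#' `manifest.csv` when present, otherwise set to `NA`.
#'
#' @param root dataset directory.
#' @return a `synth_dataset` object.
#' @export
read_image_folder <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset directory '%s' does not exist", root))
  read_png_gray <- function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im
  }
  read_classdir <- function(split) {
    classes <- sort(list.dirs(file.path(root, split), recursive = FALSE,
                              full.names = FALSE))
    imgs <- list(); labels <- integer(0)
    for (k in seq_along(classes)) {
      fs <- sort(list.files(file.path(root, split, classes[k]),
                            pattern = "\\.png$", full.names = TRUE))
      for (f in fs) imgs[[length(imgs) + 1L]] <- read_png_gray(f)
      labels <- c(labels, rep(k - 1L, length(fs)))
    }
    d <- dim(imgs[[1]])
    arr <- array(0, c(d[1], d[2], length(imgs)))
    for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
    list(images = arr, labels = labels, classes = classes)
  }
  lab <- read_classdir("labeled")
  tst <- read_classdir("test")
  ufs <- sort(list.files(file.path(root, "unlabeled"), pattern = "\\.png$",
                         full.names = TRUE))
  uimgs <- array(0, c(dim(lab$images)[1], dim(lab$images)[2], length(ufs)))
  for (i in seq_along(ufs)) uimgs[, , i] <- read_png_gray(ufs[i])
  hidden <- rep(NA_integer_, length(ufs))
  mf <- file.path(root, "manifest.csv")
  if (file.exists(mf)) {
    man <- read.csv(mf)
    um <- man[man$split == "unlabeled", ]
    um <- um[order(um$file), ]
    if (nrow(um) == length(ufs)) hidden <- um$hidden_label
  }
  structure(list(labeled = list(images = lab$images, labels = lab$labels),
                 unlabeled = list(images = uimgs, hidden_labels = hidden),
                 test = list(images = tst$images, labels = tst$labels),
                 class_names = lab$classes, spec = NULL),
            class = "synth_dataset")
}
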