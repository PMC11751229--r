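#' Configure the four-stage lightweight encoder
#'
#' The encoder is a compact four-stage convolutional network in the
#' re-parameterizable style: every block carries a depthwise 3x3 unit with
#' parallel 1x1 and identity branches during training (each branch followed
#' by batch normalization), and a pointwise expansion/projection pair
#' (expansion ratio 2). The parallel branches can be algebraically fused
#' into a single depthwise 3x3 convolution for inference with
#' [fuse_reparam()]. The feature map after stage 3 (the "tap") feeds the
#' DAMix block; global average pooling of stage 4 yields the embedding used
#' by the classifier heads.
#'
#' @param in_channels number of input image channels (grayscale = 1).
#' @param stage_widths integer vector of 4 channel widths.
#' @param stage_depths integer vector of 4 block counts per stage.
#' @param stage_strides integer vector of 4 downsampling strides (first
#'   block of each stage).
#' @param use_reparam_branches if `TRUE`, blocks are built with the parallel
#'   training-time branches; if `FALSE`, with a single depthwise kernel.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(in_channels = 1L,
                           stage_widths = c(32L, 64L, 128L, 256L),
                           stage_depths = c(1L, 1L, 2L, 1L),
                           stage_strides = c(2L, 2L, 2L, 2L),
                           use_reparam_branches = TRUE) {
  stopifnot(length(stage_widths) == 4L, length(stage_depths) == 4L,
            length(stage_strides) == 4L,
            all(stage_widths > 0), all(stage_depths > 0), all(stage_strides > 0))
  structure(list(in_channels = as.integer(in_channels),
                 stage_widths = as.integer(stage_widths),
                 stage_depths = as.integer(stage_depths),
                 stage_strides = as.integer(stage_strides),
                 embedding_dim = as.integer(stage_widths[4]),
                 use_reparam_branches = isTRUE(use_reparam_branches)),
            class = "encoder_config")
}

# He-style initialization for a fan_in-sized receptive field
he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

#' Build an encoder with deterministic initialization
#'
#' @param config an [encoder_config()].
#' @param seed integer seed controlling parameter initialization.
#' @return an object of class `spemix_encoder` holding trainable parameters
#'   (`par`), batch-normalization running statistics (`buf`), and the block
#'   plan. The stage-3 tap has spatial size `input / prod(strides[1:3])`.
#' @export
build_encoder <- function(config = encoder_config(), seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  blocks <- list()
  cin <- config$in_channels
  for (s in 1:4) {
    for (j in seq_len(config$stage_depths[s])) {
      stride <- if (j == 1L) config$stage_strides[s] else 1L
      cout <- config$stage_widths[s]
      blocks[[length(blocks) + 1L]] <- list(
        name = sprintf("s%db%d", s, j), cin = cin, cout = cout,
        stride = stride, residual = (stride == 1L && cin == cout),
        stage = s)
      cin <- cout
    }
  }
  tap_block <- max(which(vapply(blocks, `[[`, 1L, "stage") == 3L))
  par <- list(); buf <- list()
  with_seed(seed, {
    for (bl in blocks) {
      p <- bl$name; C <- bl$cin; Ch <- 2L * bl$cout
      par[[paste0(p, ".dw.k3")]] <- matrix(he_init(C * 9L, 9L), C, 9L)
      if (config$use_reparam_branches) {
        par[[paste0(p, ".dw.k1")]] <- he_init(C, 1L)
        for (br in c("bn3", "bn1", if (bl$stride == 1L) "bnid")) {
          par[[paste0(p, ".dw.", br, ".g")]] <- rep(1, C)
          par[[paste0(p, ".dw.", br, ".b")]] <- rep(0, C)
          buf[[paste0(p, ".dw.", br, ".rm")]] <- rep(0, C)
          buf[[paste0(p, ".dw.", br, ".rv")]] <- rep(1, C)
        }
      } else {
        par[[paste0(p, ".dw.bn3.g")]] <- rep(1, C)
        par[[paste0(p, ".dw.bn3.b")]] <- rep(0, C)
        buf[[paste0(p, ".dw.bn3.rm")]] <- rep(0, C)
        buf[[paste0(p, ".dw.bn3.rv")]] <- rep(1, C)
      }
      par[[paste0(p, ".pw1.W")]] <- matrix(he_init(Ch * C, C), Ch, C)
      par[[paste0(p, ".pw1.bn.g")]] <- rep(1, Ch)
      par[[paste0(p, ".pw1.bn.b")]] <- rep(0, Ch)
      buf[[paste0(p, ".pw1.bn.rm")]] <- rep(0, Ch)
      buf[[paste0(p, ".pw1.bn.rv")]] <- rep(1, Ch)
      par[[paste0(p, ".pw2.W")]] <- matrix(he_init(bl$cout * Ch, Ch), bl$cout, Ch)
      par[[paste0(p, ".pw2.bn.g")]] <- rep(1, bl$cout)
      par[[paste0(p, ".pw2.bn.b")]] <- rep(0, bl$cout)
      buf[[paste0(p, ".pw2.bn.rm")]] <- rep(0, bl$cout)
      buf[[paste0(p, ".pw2.bn.rv")]] <- rep(1, bl$cout)
    }
  })
  structure(list(config = config, blocks = blocks, tap_block = tap_block,
                 par = par, buf = buf, fused = FALSE),
            class = "spemix_encoder")
}

total_stride <- function(config, through_stage = 4L) {
  prod(config$stage_strides[seq_len(through_stage)])
}

# one rep-style block; returns y, cache, updated buffers
block_fwd <- function(enc, bl, x, train, keep_cache) {
  par <- enc$par; buf <- enc$buf; p <- bl$name
  cache <- list()
  if (enc$fused) {
    s <- dw3_fwd(x, par[[paste0(p, ".dw.k3f")]], bl$stride,
                 bias = par[[paste0(p, ".dw.bf")]])
  } else if (enc$config$use_reparam_branches) {
    a3 <- dw3_fwd(x, par[[paste0(p, ".dw.k3")]], bl$stride)
    b3 <- bn_fwd(a3, par[[paste0(p, ".dw.bn3.g")]], par[[paste0(p, ".dw.bn3.b")]],
                 buf[[paste0(p, ".dw.bn3.rm")]], buf[[paste0(p, ".dw.bn3.rv")]], train)
    buf[[paste0(p, ".dw.bn3.rm")]] <- b3$rm; buf[[paste0(p, ".dw.bn3.rv")]] <- b3$rv
    a1 <- dw1_fwd(x, par[[paste0(p, ".dw.k1")]], bl$stride)
    b1 <- bn_fwd(a1, par[[paste0(p, ".dw.bn1.g")]], par[[paste0(p, ".dw.bn1.b")]],
                 buf[[paste0(p, ".dw.bn1.rm")]], buf[[paste0(p, ".dw.bn1.rv")]], train)
    buf[[paste0(p, ".dw.bn1.rm")]] <- b1$rm; buf[[paste0(p, ".dw.bn1.rv")]] <- b1$rv
    if (bl$stride == 1L) {
      bid <- bn_fwd(x, par[[paste0(p, ".dw.bnid.g")]], par[[paste0(p, ".dw.bnid.b")]],
                    buf[[paste0(p, ".dw.bnid.rm")]], buf[[paste0(p, ".dw.bnid.rv")]], train)
      buf[[paste0(p, ".dw.bnid.rm")]] <- bid$rm; buf[[paste0(p, ".dw.bnid.rv")]] <- bid$rv
      s <- .add_relu(b3$y, b1$y, bid$y)
      if (keep_cache) cache$bnid <- bid$cache
    } else {
      s <- .add_relu(b3$y, b1$y, NULL)
    }
    dim(s) <- dim(b3$y)
    if (keep_cache) { cache$bn3 <- b3$cache; cache$bn1 <- b1$cache }
    r0 <- s
  } else {
    a3 <- dw3_fwd(x, par[[paste0(p, ".dw.k3")]], bl$stride)
    b3 <- bn_fwd(a3, par[[paste0(p, ".dw.bn3.g")]], par[[paste0(p, ".dw.bn3.b")]],
                 buf[[paste0(p, ".dw.bn3.rm")]], buf[[paste0(p, ".dw.bn3.rv")]], train)
    buf[[paste0(p, ".dw.bn3.rm")]] <- b3$rm; buf[[paste0(p, ".dw.bn3.rv")]] <- b3$rv
    s <- b3$y
    if (keep_cache) cache$bn3 <- b3$cache
    r0 <- relu_fwd(s)
  }
  if (enc$fused) r0 <- relu_fwd(s)
  h1 <- pw_fwd(r0, par[[paste0(p, ".pw1.W")]])
  bp1 <- bn_relu_fwd(h1, par[[paste0(p, ".pw1.bn.g")]], par[[paste0(p, ".pw1.bn.b")]],
                     buf[[paste0(p, ".pw1.bn.rm")]], buf[[paste0(p, ".pw1.bn.rv")]], train)
  buf[[paste0(p, ".pw1.bn.rm")]] <- bp1$rm; buf[[paste0(p, ".pw1.bn.rv")]] <- bp1$rv
  r1 <- bp1$y
  h2 <- pw_fwd(r1, par[[paste0(p, ".pw2.W")]])
  bp2 <- bn_fwd(h2, par[[paste0(p, ".pw2.bn.g")]], par[[paste0(p, ".pw2.bn.b")]],
                buf[[paste0(p, ".pw2.bn.rm")]], buf[[paste0(p, ".pw2.bn.rv")]], train)
  buf[[paste0(p, ".pw2.bn.rm")]] <- bp2$rm; buf[[paste0(p, ".pw2.bn.rv")]] <- bp2$rv
  y <- if (bl$residual) bp2$y + x else bp2$y
  if (keep_cache) {
    cache$x <- x; cache$r0y <- r0
    cache$pw1_bn <- bp1$cache; cache$r1y <- r1
    cache$pw2_bn <- bp2$cache
  }
  list(y = y, cache = cache, buf = buf)
}

block_bwd <- function(enc, bl, cache, gy) {
  par <- enc$par; p <- bl$name
  grads <- list()
  gx_res <- if (bl$residual) gy else NULL
  g2 <- bn_bwd(cache$pw2_bn, par[[paste0(p, ".pw2.bn.g")]], gy)
  grads[[paste0(p, ".pw2.bn.g")]] <- g2$gg
  grads[[paste0(p, ".pw2.bn.b")]] <- g2$gb
  gp2 <- pw_bwd(cache$r1y, par[[paste0(p, ".pw2.W")]], g2$gx)
  grads[[paste0(p, ".pw2.W")]] <- gp2$gW
  g1 <- bn_relu_bwd(cache$pw1_bn, par[[paste0(p, ".pw1.bn.g")]], gp2$gx)
  grads[[paste0(p, ".pw1.bn.g")]] <- g1$gg
  grads[[paste0(p, ".pw1.bn.b")]] <- g1$gb
  gp1 <- pw_bwd(cache$r0y, par[[paste0(p, ".pw1.W")]], g1$gx)
  grads[[paste0(p, ".pw1.W")]] <- gp1$gW
  gs <- relu_bwd(cache$r0y, gp1$gx)
  x <- cache$x
  if (enc$config$use_reparam_branches && !enc$fused) {
    g3 <- bn_bwd(cache$bn3, par[[paste0(p, ".dw.bn3.g")]], gs)
    grads[[paste0(p, ".dw.bn3.g")]] <- g3$gg
    grads[[paste0(p, ".dw.bn3.b")]] <- g3$gb
    gd3 <- dw3_bwd(x, par[[paste0(p, ".dw.k3")]], g3$gx, bl$stride)
    grads[[paste0(p, ".dw.k3")]] <- gd3$gk
    gx <- gd3$gx
    gb1 <- bn_bwd(cache$bn1, par[[paste0(p, ".dw.bn1.g")]], gs)
    grads[[paste0(p, ".dw.bn1.g")]] <- gb1$gg
    grads[[paste0(p, ".dw.bn1.b")]] <- gb1$gb
    gd1 <- dw1_bwd(x, par[[paste0(p, ".dw.k1")]], gb1$gx, bl$stride)
    grads[[paste0(p, ".dw.k1")]] <- gd1$gk
    gx <- gx + gd1$gx
    if (bl$stride == 1L) {
      gid <- bn_bwd(cache$bnid, par[[paste0(p, ".dw.bnid.g")]], gs)
      grads[[paste0(p, ".dw.bnid.g")]] <- gid$gg
      grads[[paste0(p, ".dw.bnid.b")]] <- gid$gb
      gx <- gx + gid$gx
    }
  } else {
    g3 <- bn_bwd(cache$bn3, par[[paste0(p, ".dw.bn3.g")]], gs)
    grads[[paste0(p, ".dw.bn3.g")]] <- g3$gg
    grads[[paste0(p, ".dw.bn3.b")]] <- g3$gb
    gd3 <- dw3_bwd(x, par[[paste0(p, ".dw.k3")]], g3$gx, bl$stride)
    grads[[paste0(p, ".dw.k3")]] <- gd3$gk
    gx <- gd3$gx
  }
  if (!is.null(gx_res)) gx <- gx + gx_res
  list(gx = gx, grads = grads)
}

# full encoder pass; returns tap, embedding, caches, updated buffers
enc_forward <- function(enc, x, train = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  ts <- total_stride(enc$config)
  if (d[1] != enc$config$in_channels) {
    stop(sprintf("expected %d input channel(s), got %d",
                 enc$config$in_channels, d[1]))
  }
  if (d[2] %% ts != 0L || d[3] %% ts != 0L) {
    stop(sprintf("input spatial size (%d x %d) must be divisible by the total stride %d",
                 d[2], d[3], ts))
  }
  caches <- vector("list", length(enc$blocks))
  tap <- NULL
  for (i in seq_along(enc$blocks)) {
    out <- block_fwd(enc, enc$blocks[[i]], x, train, keep_cache)
    x <- out$y
    enc$buf <- out$buf
    if (keep_cache) caches[[i]] <- out$cache
    if (i == enc$tap_block) tap <- x
  }
  g <- gap_fwd(x)
  list(tap = tap, emb = g$emb, caches = caches, gap_hw = g$hw,
       buf = enc$buf, B = d[4])
}

# backward from an embedding gradient; returns parameter grads and the
# gradient with respect to the input image batch
enc_backward <- function(enc, fw, gemb) {
  gx <- gap_bwd(gemb, fw$gap_hw, fw$B)
  grads <- list()
  for (i in rev(seq_along(enc$blocks))) {
    bb <- block_bwd(enc, enc$blocks[[i]], fw$caches[[i]], gx)
    gx <- bb$gx
    grads[names(bb$grads)] <- bb$grads
  }
  list(grads = grads, gx = gx)
}

#' Run the encoder on an image batch
#'
#' Returns both the stage-3 tap feature (the input to the DAMix block) and
#' the pooled embedding from a single pass.
#'
#' @param encoder a [build_encoder()] result.
#' @param batch images as an `H x W` matrix, `H x W x B` array, or an
#'   internal `C x H x W x B` array, pixel values in `[0, 1]`.
#' @param train use batch statistics in normalization layers (`TRUE`) or
#'   running statistics (`FALSE`, inference mode).
#' @return list with elements `tap` (`C x h x w x B` feature array) and
#'   `embedding` (`embedding_dim x B` matrix).
#' @export
forward_features <- function(encoder, batch, train = FALSE) {
  x <- as_chwb(batch)
  fw <- enc_forward(encoder, x, train = train, keep_cache = FALSE)
  list(tap = fw$tap, embedding = fw$emb)
}

#' Fuse re-parameterization branches for inference
#'
#' Folds each block's parallel depthwise branches (3x3 + 1x1 + identity,
#' each with its batch normalization) into a single depthwise 3x3
#' convolution with bias, using the running normalization statistics. The
#' fused encoder is inference-only and reproduces the branched encoder's
#' inference-mode outputs up to floating-point error.
#'
#' @param encoder a branched [build_encoder()] result.
#' @return the fused encoder (strictly fewer trainable parameters).
#' @export
fuse_reparam <- function(encoder) {
  stopifnot(inherits(encoder, "spemix_encoder"))
  if (encoder$fused) {
    warning("encoder is already fused; returning it unchanged")
    return(encoder)
  }
  if (!encoder$config$use_reparam_branches) {
    stop("encoder was built without re-parameterization branches")
  }
  par <- encoder$par; buf <- encoder$buf
  newpar <- list()
  for (bl in encoder$blocks) {
    p <- bl$name; C <- bl$cin
    fold <- function(br) {
      g <- par[[paste0(p, ".dw.", br, ".g")]]
      b <- par[[paste0(p, ".dw.", br, ".b")]]
      rm <- buf[[paste0(p, ".dw.", br, ".rm")]]
      rv <- buf[[paste0(p, ".dw.", br, ".rv")]]
      s <- g / sqrt(rv + BN_EPS)
      list(scale = s, bias = b - rm * s)
    }
    f3 <- fold("bn3")
    k <- par[[paste0(p, ".dw.k3")]] * f3$scale
    bias <- f3$bias
    f1 <- fold("bn1")
    k[, 5L] <- k[, 5L] + par[[paste0(p, ".dw.k1")]] * f1$scale  # tap (0,0)
    bias <- bias + f1$bias
    if (bl$stride == 1L) {
      fid <- fold("bnid")
      k[, 5L] <- k[, 5L] + fid$scale
      bias <- bias + fid$bias
    }
    newpar[[paste0(p, ".dw.k3f")]] <- k
    newpar[[paste0(p, ".dw.bf")]] <- bias
    for (nm in c("pw1.W", "pw1.bn.g", "pw1.bn.b", "pw2.W", "pw2.bn.g", "pw2.bn.b")) {
      newpar[[paste0(p, ".", nm)]] <- par[[paste0(p, ".", nm)]]
    }
  }
  keep <- grepl("\\.pw[12]\\.bn\\.r[mv]$", names(buf))
  encoder$par <- newpar
  encoder$buf <- buf[keep]
  encoder$fused <- TRUE
  encoder
}

#' Count trainable parameters
#'
#' Sums the number of scalar trainable parameters across the given parts.
#' Accepts encoders, head lists, DAMix parameter lists, plain numeric
#' arrays, or (nested) lists of these. Normalization running statistics are
#' buffers, not parameters, and are not counted.
#'
#' @param ... model parts.
#' @return integer total.
#' @export
count_parameters <- function(...) {
  parts <- list(...)
  count_one <- function(x) {
    if (is.null(x)) return(0)
    if (inherits(x, "spemix_encoder")) return(count_one(x$par))
    if (inherits(x, "spemix")) {
      st <- x$state
      return(count_one(st$student$enc) + count_one(st$student$heads) +
               count_one(st$damix))
    }
    if (inherits(x, "spemix_heads")) {
      return(count_one(x$close) + count_one(x$multi) + count_one(x$open))
    }
    if (is.numeric(x)) return(length(x))
    if (is.list(x)) return(sum(vapply(x, count_one, numeric(1))))
    0
  }
  as.integer(sum(vapply(parts, count_one, numeric(1))))
}
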