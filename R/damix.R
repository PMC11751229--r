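#' DAMix configuration
#'
#' Settings of the dynamic-attention mixup block: region grid size `S`
#' (the tap feature is tokenized into `S^2` square regions), the number of
#' routed regions `k` attended per query region, the Beta concentration
#' `alpha` of the mixing-ratio distribution, and the encoder stage whose
#' feature map feeds the block.
#'
#' @param S regions per side; `NULL` picks 7 when the tap size is divisible
#'   by 7, otherwise 2 (clipped to a divisor of the tap size).
#' @param topk routed regions per query region; clipped to `S^2`.
#' @param alpha Beta concentration for the mixing ratio (`lambda ~
#'   Beta(alpha, alpha)`).
#' @param tap_stage encoder stage feeding the block (3: behind the third
#'   stage).
#' @export
damix_config <- function(S = NULL, topk = 4L, alpha = 1.0, tap_stage = 3L) {
  if (!is.null(S)) stopifnot(S >= 1)
  stopifnot(topk >= 1, alpha > 0)
  structure(list(S = if (is.null(S)) NULL else as.integer(S),
                 topk = as.integer(topk), alpha = alpha,
                 tap_stage = as.integer(tap_stage)),
            class = "damix_config")
}

pick_S <- function(cfg_S, H) {
  if (!is.null(cfg_S)) {
    if (H %% cfg_S != 0L) {
      stop(sprintf("S = %d does not divide the tap size %d; valid divisors: %s",
                   cfg_S, H, paste(which(H %% seq_len(H) == 0), collapse = ", ")))
    }
    return(cfg_S)
  }
  if (H %% 7L == 0L) 7L else if (H %% 2L == 0L) 2L else 1L
}

#' Sample a mixing ratio
#'
#' Draws `n` mixing ratios from `Beta(alpha, alpha)`, clamped to
#' `[1e-4, 1 - 1e-4]` so that both images always contribute to the mix.
#'
#' @param alpha positive Beta concentration.
#' @param n number of draws.
#' @return numeric vector in (0, 1).
#' @export
sample_lambda <- function(alpha, n = 1L) {
  stop_if_not_scalar(alpha, "alpha")
  if (alpha <= 0) stop("`alpha` must be > 0")
  pmin(pmax(rbeta(n, alpha, alpha), 1e-4), 1 - 1e-4)
}

# permutation taking flat spatial order (h fastest) to region-grouped order
region_perm <- function(H, W, S) {
  nh <- H %/% S; nw <- W %/% S
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  rid <- ceiling(h / nh) + S * (ceiling(w / nw) - 1L)
  order(rid, w, h)
}

#' Tokenize a feature map into square regions
#'
#' Splits an `H x W x C` feature map into `S^2` square regions, each
#' holding `H*W/S^2` spatial positions of `C` channels. The split is
#' lossless: [deregionize()] restores the original map exactly.
#'
#' @param feature `H x W x C` array.
#' @param S regions per side; must divide both `H` and `W`.
#' @return object of class `region_token_grid`: a `S^2 x (HW/S^2) x C`
#'   token array plus the origin geometry.
#' @export
regionize <- function(feature, S) {
  d <- dim(feature)
  stopifnot(length(d) == 3L)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (H %% S != 0L || W %% S != 0L) {
    stop(sprintf("S = %d must divide H = %d and W = %d; valid common divisors: %s",
                 S, H, W,
                 paste(which(H %% seq_len(min(H, W)) == 0 & W %% seq_len(min(H, W)) == 0),
                       collapse = ", ")))
  }
  n <- (H * W) %/% (S * S)
  perm <- region_perm(H, W, S)
  X <- matrix(feature, H * W, C)[perm, , drop = FALSE]
  tokens <- array(0, c(S * S, n, C))
  for (r in seq_len(S * S)) tokens[r, , ] <- X[((r - 1L) * n + 1L):(r * n), ]
  structure(list(tokens = tokens, S = as.integer(S), H = H, W = W, C = C,
                 perm = perm),
            class = "region_token_grid")
}

#' Restore a feature map from region tokens
#'
#' @param grid a [regionize()] result.
#' @return the original `H x W x C` array.
#' @export
deregionize <- function(grid) {
  stopifnot(inherits(grid, "region_token_grid"))
  n <- dim(grid$tokens)[2]
  X <- matrix(0, grid$H * grid$W, grid$C)
  for (r in seq_len(grid$S^2)) X[((r - 1L) * n + 1L):(r * n), ] <- grid$tokens[r, , ]
  Xf <- X[order(grid$perm), , drop = FALSE]
  array(Xf, c(grid$H, grid$W, grid$C))
}

# ---- routed attention core (single image, region-ordered N x C matrix) ------

dynattn_fwd <- function(X, Wq, Wk, Wv, S, k, n) {
  Tn <- S * S
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  scale <- sqrt(ncol(X))
  if (k == Tn) {
    # every region is routed to every other: identical to dense attention
    A <- softmax_rows(tcrossprod(Q, K) / scale)
    return(list(O = A %*% V,
                cache = list(Q = Q, K = K, V = V, A = A, dense = TRUE,
                             S = S, k = k, n = n, scale = scale)))
  }
  grp <- rep(seq_len(Tn), each = n)
  Qa <- rowsum(Q, grp, reorder = FALSE) / n
  Ka <- rowsum(K, grp, reorder = FALSE) / n
  P <- Qa %*% t(Ka)
  O <- matrix(0, nrow(X), ncol(X))
  cache <- list(Q = Q, K = K, V = V, A = vector("list", Tn), dense = FALSE,
                sel = vector("list", Tn), S = S, k = k, n = n, scale = scale)
  for (r in seq_len(Tn)) {
    idx <- order(P[r, ], decreasing = TRUE)[seq_len(k)]
    rows_q <- ((r - 1L) * n + 1L):(r * n)
    rows_kv <- as.vector(vapply(idx, function(j) ((j - 1L) * n + 1L):(j * n),
                                integer(n)))
    A <- softmax_rows(Q[rows_q, , drop = FALSE] %*%
                        t(K[rows_kv, , drop = FALSE]) / scale)
    O[rows_q, ] <- A %*% V[rows_kv, , drop = FALSE]
    cache$A[[r]] <- A
    cache$sel[[r]] <- rows_kv
  }
  list(O = O, cache = cache)
}

dynattn_bwd <- function(X, Wq, Wk, Wv, cache, dO) {
  n <- cache$n; Tn <- cache$S^2; scale <- cache$scale
  if (isTRUE(cache$dense)) {
    A <- cache$A
    dA <- tcrossprod(dO, cache$V)
    dV <- crossprod(A, dO)
    dS <- A * (dA - rowSums(dA * A))
    dQ <- dS %*% cache$K / scale
    dK <- crossprod(dS, cache$Q) / scale
    return(list(gWq = crossprod(X, dQ), gWk = crossprod(X, dK),
                gWv = crossprod(X, dV)))
  }
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  for (r in seq_len(Tn)) {
    rows_q <- ((r - 1L) * n + 1L):(r * n)
    rows_kv <- cache$sel[[r]]
    A <- cache$A[[r]]
    dOr <- dO[rows_q, , drop = FALSE]
    dA <- dOr %*% t(cache$V[rows_kv, , drop = FALSE])
    dV[rows_kv, ] <- dV[rows_kv, ] + t(A) %*% dOr
    dS <- A * (dA - rowSums(dA * A))
    dQ[rows_q, ] <- dQ[rows_q, ] + dS %*% cache$K[rows_kv, , drop = FALSE] / scale
    dK[rows_kv, ] <- dK[rows_kv, ] + t(dS) %*% cache$Q[rows_q, , drop = FALSE] / scale
  }
  list(gWq = crossprod(X, dQ), gWk = crossprod(X, dK), gWv = crossprod(X, dV))
}

#' Dynamic (top-k routed) attention over region tokens
#'
#' Tokenizes the feature map into `S^2` regions, scores region pairs by the
#' dot product of region-averaged queries and keys, and restricts each
#' query region's token-level scaled dot-product attention to its `k` most
#' similar regions. A residual connection adds the input.
#'
#' @param feature `H x W x C` array.
#' @param params list with `Wq`, `Wk`, `Wv` (`C x C` projection matrices).
#' @param S regions per side.
#' @param k routed regions per query region, `1 <= k <= S^2`.
#' @return refined `H x W x C` feature map.
#' @export
dynamic_attention <- function(feature, params, S, k) {
  d <- dim(feature)
  stopifnot(length(d) == 3L)
  if (k < 1 || k > S * S) {
    stop(sprintf("`k` must be in [1, S^2] = [1, %d], got %s", S * S, k))
  }
  grid <- regionize(feature, S)
  n <- dim(grid$tokens)[2]
  X <- matrix(feature, d[1] * d[2], d[3])[grid$perm, , drop = FALSE]
  out <- dynattn_fwd(X, params$Wq, params$Wk, params$Wv, S, k, n)
  O <- matrix(0, d[1] * d[2], d[3])
  O[grid$perm, ] <- out$O
  feature + array(O, d)
}

# ---- lambda-embedding blocks -------------------------------------------------

IN_EPS <- 1e-5

# block: concat a constant-lambda channel, 1x1 conv back to C channels,
# instance normalization (per channel over positions, no affine)
inblock_fwd <- function(Z, lam, W, b) {
  Xa <- cbind(Z, lam)
  pre <- Xa %*% t(W) + matrix(b, nrow(Z), length(b), byrow = TRUE)
  mu <- colMeans(pre)
  v <- colMeans(pre * pre) - mu * mu
  invstd <- 1 / sqrt(pmax(v, 0) + IN_EPS)
  yhat <- sweep(sweep(pre, 2L, mu), 2L, invstd, `*`)
  list(Y = yhat, cache = list(Xa = Xa, yhat = yhat, invstd = invstd))
}

inblock_bwd <- function(cache, W, dY) {
  yhat <- cache$yhat
  dg_term <- colMeans(dY * yhat)
  dpre <- sweep(sweep(dY, 2L, colMeans(dY)) - sweep(yhat, 2L, dg_term, `*`),
                2L, cache$invstd, `*`)
  C <- ncol(yhat)
  list(gW = crossprod(dpre, cache$Xa), gb = colSums(dpre),
       dZ = dpre %*% W[, seq_len(C), drop = FALSE])
}

#' Embed a mixing ratio into a feature map
#'
#' Concatenates one constant-`lambda` channel to the feature, applies a
#' learned pointwise projection back to `C` channels, and instance-
#' normalizes each channel. This is the shared structure of the Query, Key
#' and Value blocks of the mask generator.
#'
#' @param feature `H x W x C` array.
#' @param lambda mixing ratio in (0, 1).
#' @param block list with `W` (`C x (C+1)` weights) and `b` (length-`C`
#'   bias).
#' @return `H x W x C` array.
#' @export
embed_lambda <- function(feature, lambda, block) {
  d <- dim(feature)
  stopifnot(length(d) == 3L, lambda > 0, lambda < 1)
  Z <- matrix(feature, d[1] * d[2], d[3])
  out <- inblock_fwd(Z, lambda, block$W, block$b)
  array(out$Y, d)
}

# interpolation matrix for 1-D bilinear resize (half-pixel-center mapping)
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out + 0.5
    l <- floor(s); w <- s - l
    l0 <- min(max(l, 1L), n_in); l1 <- min(max(l + 1L, 1L), n_in)
    A[i, l0] <- A[i, l0] + (1 - w)
    A[i, l1] <- A[i, l1] + w
  }
  A
}

#' Generate the mixed mask from a pair of refined features
#'
#' Cross-attention between the lambda-embedded key of the first feature and
#' the lambda-embedded query of the second, softmax over key positions,
#' multiplied by the lambda-embedded value of the first feature, collapsed
#' to one channel, passed through a sigmoid, and bilinearly upsampled to
#' the image grid. The complementary mask for the second image is `1 - M`
#' by construction.
#'
#' @param z1p,z2p refined `h x w x C` features of the value image and of
#'   its mixing partner.
#' @param lambda mixing ratio in (0, 1).
#' @param blocks list with elements `qb`, `kb`, `vb` (each `list(W, b)`)
#'   and `proj` (`list(w, b)`: length-`C` weights and scalar bias).
#' @param out_size target `c(H, W)` of the mask (the image resolution).
#' @return `H x W` mask matrix with entries strictly in (0, 1).
#' @export
generate_mask <- function(z1p, z2p, lambda, blocks, out_size = dim(z1p)[1:2] * 8L) {
  d <- dim(z1p)
  if (!identical(d, dim(z2p))) stop("z1p and z2p must have identical shapes")
  stopifnot(lambda > 0, lambda < 1)
  Z1 <- matrix(z1p, d[1] * d[2], d[3])
  Z2 <- matrix(z2p, d[1] * d[2], d[3])
  fw <- maskgen_fwd(Z1, Z2, lambda, blocks, d[1], d[2], out_size)
  fw$M
}

# mask generator forward on flattened features (N x C); returns caches for
# the training backward pass
maskgen_fwd <- function(Z1, Z2, lam, blk, h, w, out_size) {
  C <- ncol(Z1)
  kb <- inblock_fwd(Z1, lam, blk$kb$W, blk$kb$b)
  qb <- inblock_fwd(Z2, lam, blk$qb$W, blk$qb$b)
  vb <- inblock_fwd(Z1, lam, blk$vb$W, blk$vb$b)
  P2 <- softmax_rows(qb$Y %*% t(kb$Y) / sqrt(C))
  Fm <- P2 %*% vb$Y
  L <- as.vector(Fm %*% blk$proj$w) + blk$proj$b
  Ml <- 1 / (1 + exp(-L))
  A <- bilinear_matrix(h, out_size[1])
  Bm <- bilinear_matrix(w, out_size[2])
  M <- A %*% matrix(Ml, h, w) %*% t(Bm)
  list(M = M,
       cache = list(kb = kb$cache, qb = qb$cache, vb = vb$cache,
                    Km = kb$Y, Qm = qb$Y, Vm = vb$Y, P2 = P2, Fm = Fm,
                    Ml = Ml, A = A, Bm = Bm, h = h, w = w, C = C))
}

maskgen_bwd <- function(cache, blk, dM) {
  C <- cache$C
  dMl <- as.vector(t(cache$A) %*% dM %*% cache$Bm)
  dL <- dMl * cache$Ml * (1 - cache$Ml)
  dF <- outer(dL, blk$proj$w)
  gproj_w <- as.vector(crossprod(cache$Fm, dL))
  gproj_b <- sum(dL)
  dP2 <- dF %*% t(cache$Vm)
  dVm <- crossprod(cache$P2, dF)
  dS <- cache$P2 * (dP2 - rowSums(dP2 * cache$P2))
  dQm <- dS %*% cache$Km / sqrt(C)
  dKm <- crossprod(dS, cache$Qm) / sqrt(C)
  gq <- inblock_bwd(cache$qb, blk$qb$W, dQm)
  gk <- inblock_bwd(cache$kb, blk$kb$W, dKm)
  gv <- inblock_bwd(cache$vb, blk$vb$W, dVm)
  list(gqb.W = gq$gW, gqb.b = gq$gb, gkb.W = gk$gW, gkb.b = gk$gb,
       gvb.W = gv$gW, gvb.b = gv$gb, gproj.w = gproj_w, gproj.b = gproj_b,
       dZ1 = gk$dZ + gv$dZ, dZ2 = gq$dZ)
}

#' Pixel-level efficient mixup
#'
#' Convex pixelwise combination `M * u1 + (1 - M) * u2`.
#'
#' @param u1,u2 image batches (`H x W` matrices or `H x W x B` arrays) with
#'   matching shapes.
#' @param M mask in `[0, 1]`, `H x W` (broadcast over the batch) or the
#'   full batch shape.
#' @return mixed images, same shape as `u1`.
#' @export
efficient_mixup <- function(u1, u2, M) {
  if (!identical(dim(u1), dim(u2))) stop("u1 and u2 must have identical shapes")
  if (any(M < 0) || any(M > 1)) stop("mask values must lie in [0, 1]")
  if (length(dim(u1)) == 3L && length(dim(M)) == 2L) {
    M <- array(M, dim(u1))
  }
  M * u1 + (1 - M) * u2
}

# ---- DAMix parameter bundle and batched training path -----------------------

damix_init <- function(C, seed = 1L) {
  with_seed(seed, {
    sd1 <- 1 / sqrt(C); sd2 <- 1 / sqrt(C + 1)
    structure(list(
      Wq = matrix(rnorm(C * C, sd = sd1), C, C),
      Wk = matrix(rnorm(C * C, sd = sd1), C, C),
      Wv = matrix(rnorm(C * C, sd = sd1), C, C),
      qb = list(W = matrix(rnorm(C * (C + 1), sd = sd2), C, C + 1), b = numeric(C)),
      kb = list(W = matrix(rnorm(C * (C + 1), sd = sd2), C, C + 1), b = numeric(C)),
      vb = list(W = matrix(rnorm(C * (C + 1), sd = sd2), C, C + 1), b = numeric(C)),
      proj = list(w = rnorm(C, sd = sd1), b = 0)
    ), class = "spemix_damix_params")
  })
}

# batched lambda-embedding block: instance norm per (image, channel)
inb_fwd_b <- function(Zall, lam, W, b, grp, N) {
  Xa <- cbind(Zall, lam)
  pre <- Xa %*% t(W)
  pre <- pre + rep(b, each = nrow(pre))
  mu <- rowsum(pre, grp, reorder = FALSE) / N
  v <- rowsum(pre * pre, grp, reorder = FALSE) / N - mu * mu
  invstd <- 1 / sqrt(pmax(v, 0) + IN_EPS)
  isE <- invstd[grp, , drop = FALSE]
  yhat <- (pre - mu[grp, , drop = FALSE]) * isE
  list(Y = yhat, cache = list(Xa = Xa, yhat = yhat, isE = isE, grp = grp, N = N))
}

inb_bwd_b <- function(cache, W, dY) {
  yhat <- cache$yhat; grp <- cache$grp; N <- cache$N
  t1 <- rowsum(dY, grp, reorder = FALSE) / N
  t2 <- rowsum(dY * yhat, grp, reorder = FALSE) / N
  dpre <- (dY - t1[grp, , drop = FALSE] - yhat * t2[grp, , drop = FALSE]) *
    cache$isE
  C <- ncol(yhat)
  list(gW = crossprod(dpre, cache$Xa), gb = colSums(dpre),
       dZ = dpre %*% W[, seq_len(C), drop = FALSE])
}

# full DAMix pass on a pair of tap batches (C x h x w x B); taps are treated
# as detached teacher features. Returns per-image masks at image resolution.
# Token projections and lambda blocks run as single batched products; only
# the per-image attention softmaxes loop over the batch.
damix_forward <- function(par, tap1, tap2, lam, out_size, S, k) {
  d <- dim(tap1)
  C <- d[1]; h <- d[2]; w <- d[3]; B <- d[4]
  N <- h * w
  Tn <- S * S
  n <- N %/% Tn
  scale <- sqrt(C)
  perm <- region_perm(h, w, S)
  iperm <- order(perm)
  permall <- rep((seq_len(B) - 1L) * N, each = N) + rep(perm, B)
  X1 <- t(matrix(tap1, C, N * B))  # (B*N) x C, flat spatial order per image
  X2 <- t(matrix(tap2, C, N * B))
  grp <- rep(seq_len(B), each = N)

  attn_one <- function(Xr) {
    # Xr: region-ordered (B*N) x C stack
    Q <- Xr %*% par$Wq; K <- Xr %*% par$Wk; V <- Xr %*% par$Wv
    O <- matrix(0, nrow(Xr), C)
    A <- vector("list", B)
    sub <- vector("list", B)
    for (i in seq_len(B)) {
      ri <- ((i - 1L) * N + 1L):(i * N)
      if (k == Tn) {
        Ai <- softmax_rows(tcrossprod(Q[ri, , drop = FALSE],
                                      K[ri, , drop = FALSE]) / scale)
        O[ri, ] <- Ai %*% V[ri, , drop = FALSE]
        A[[i]] <- Ai
      } else {
        aa <- dynattn_fwd_cached(Q[ri, , drop = FALSE], K[ri, , drop = FALSE],
                                 V[ri, , drop = FALSE], S, k, n, scale)
        O[ri, ] <- aa$O
        sub[[i]] <- aa
      }
    }
    list(Q = Q, K = K, V = V, O = O, A = A, sub = sub)
  }
  a1 <- attn_one(X1[permall, , drop = FALSE])
  a2 <- attn_one(X2[permall, , drop = FALSE])
  ipermall <- rep((seq_len(B) - 1L) * N, each = N) + rep(iperm, B)
  Z1 <- X1 + a1$O[ipermall, , drop = FALSE]
  Z2 <- X2 + a2$O[ipermall, , drop = FALSE]

  kb <- inb_fwd_b(Z1, lam, par$kb$W, par$kb$b, grp, N)
  qb <- inb_fwd_b(Z2, lam, par$qb$W, par$qb$b, grp, N)
  vb <- inb_fwd_b(Z1, lam, par$vb$W, par$vb$b, grp, N)
  Fm <- matrix(0, B * N, C)
  P2 <- vector("list", B)
  for (i in seq_len(B)) {
    ri <- ((i - 1L) * N + 1L):(i * N)
    P2i <- softmax_rows(tcrossprod(qb$Y[ri, , drop = FALSE],
                                   kb$Y[ri, , drop = FALSE]) / scale)
    Fm[ri, ] <- P2i %*% vb$Y[ri, , drop = FALSE]
    P2[[i]] <- P2i
  }
  L <- as.vector(Fm %*% par$proj$w) + par$proj$b
  Ml <- 1 / (1 + exp(-L))
  Aup <- bilinear_matrix(h, out_size[1])
  Bup <- bilinear_matrix(w, out_size[2])
  M <- array(0, c(out_size[1], out_size[2], B))
  for (i in seq_len(B)) {
    M[, , i] <- Aup %*% matrix(Ml[((i - 1L) * N + 1L):(i * N)], h, w) %*% t(Bup)
  }
  list(M = M, perm = perm, iperm = iperm, permall = permall,
       ipermall = ipermall, grp = grp, N = N, B = B, scale = scale,
       X1r = X1[permall, , drop = FALSE], X2r = X2[permall, , drop = FALSE],
       a1 = a1, a2 = a2, kb = kb, qb = qb, vb = vb, Fm = Fm, P2 = P2,
       Ml = Ml, Aup = Aup, Bup = Bup, h = h, w = w, S = S, k = k, n = n)
}

# accumulate DAMix parameter gradients given dM (out-size x B array)
damix_backward <- function(par, fw, dM) {
  B <- fw$B; N <- fw$N; C <- ncol(fw$Fm); scale <- fw$scale
  dMl <- numeric(B * N)
  for (i in seq_len(B)) {
    dMl[((i - 1L) * N + 1L):(i * N)] <-
      as.vector(t(fw$Aup) %*% dM[, , i] %*% fw$Bup)
  }
  dL <- dMl * fw$Ml * (1 - fw$Ml)
  dF <- outer(dL, par$proj$w)
  gproj_w <- as.vector(crossprod(fw$Fm, dL))
  gproj_b <- sum(dL)
  dQm <- matrix(0, B * N, C); dKm <- dQm; dVm <- dQm
  for (i in seq_len(B)) {
    ri <- ((i - 1L) * N + 1L):(i * N)
    P2i <- fw$P2[[i]]
    dFi <- dF[ri, , drop = FALSE]
    dP2 <- tcrossprod(dFi, fw$vb$Y[ri, , drop = FALSE])
    dVm[ri, ] <- crossprod(P2i, dFi)
    dS <- P2i * (dP2 - rowSums(dP2 * P2i))
    dQm[ri, ] <- dS %*% fw$kb$Y[ri, , drop = FALSE] / scale
    dKm[ri, ] <- crossprod(dS, fw$qb$Y[ri, , drop = FALSE]) / scale
  }
  gq <- inb_bwd_b(fw$qb$cache, par$qb$W, dQm)
  gk <- inb_bwd_b(fw$kb$cache, par$kb$W, dKm)
  gv <- inb_bwd_b(fw$vb$cache, par$vb$W, dVm)
  dZ1 <- gk$dZ + gv$dZ
  dZ2 <- gq$dZ

  attn_bwd <- function(att, Xr, dZ) {
    dO <- dZ[fw$permall, , drop = FALSE]
    dQ <- matrix(0, B * N, C); dK <- dQ; dV <- dQ
    for (i in seq_len(B)) {
      ri <- ((i - 1L) * N + 1L):(i * N)
      dOi <- dO[ri, , drop = FALSE]
      if (fw$k == fw$S^2) {
        Ai <- att$A[[i]]
        dA <- tcrossprod(dOi, att$V[ri, , drop = FALSE])
        dV[ri, ] <- crossprod(Ai, dOi)
        dS <- Ai * (dA - rowSums(dA * Ai))
        dQ[ri, ] <- dS %*% att$K[ri, , drop = FALSE] / scale
        dK[ri, ] <- crossprod(dS, att$Q[ri, , drop = FALSE]) / scale
      } else {
        g <- dynattn_bwd_cached(att$sub[[i]], dOi)
        dQ[ri, ] <- g$dQ; dK[ri, ] <- g$dK; dV[ri, ] <- g$dV
      }
    }
    list(gWq = crossprod(Xr, dQ), gWk = crossprod(Xr, dK),
         gWv = crossprod(Xr, dV))
  }
  g1 <- attn_bwd(fw$a1, fw$X1r, dZ1)
  g2 <- attn_bwd(fw$a2, fw$X2r, dZ2)
  list(Wq = g1$gWq + g2$gWq, Wk = g1$gWk + g2$gWk, Wv = g1$gWv + g2$gWv,
       qb.W = gq$gW, qb.b = gq$gb, kb.W = gk$gW, kb.b = gk$gb,
       vb.W = gv$gW, vb.b = gv$gb, proj.w = gproj_w, proj.b = gproj_b)
}

# routed (k < S^2) attention on pre-projected Q, K, V of one image
dynattn_fwd_cached <- function(Q, K, V, S, k, n, scale) {
  Tn <- S * S
  grp <- rep(seq_len(Tn), each = n)
  Qa <- rowsum(Q, grp, reorder = FALSE) / n
  Ka <- rowsum(K, grp, reorder = FALSE) / n
  P <- Qa %*% t(Ka)
  O <- matrix(0, nrow(Q), ncol(Q))
  A <- vector("list", Tn); sel <- vector("list", Tn)
  for (r in seq_len(Tn)) {
    idx <- order(P[r, ], decreasing = TRUE)[seq_len(k)]
    rows_q <- ((r - 1L) * n + 1L):(r * n)
    rows_kv <- as.vector(vapply(idx, function(j) ((j - 1L) * n + 1L):(j * n),
                                integer(n)))
    Ar <- softmax_rows(Q[rows_q, , drop = FALSE] %*%
                         t(K[rows_kv, , drop = FALSE]) / scale)
    O[rows_q, ] <- Ar %*% V[rows_kv, , drop = FALSE]
    A[[r]] <- Ar; sel[[r]] <- rows_kv
  }
  list(O = O, Q = Q, K = K, V = V, A = A, sel = sel, n = n, Tn = Tn,
       scale = scale)
}

dynattn_bwd_cached <- function(cc, dO) {
  n <- cc$n
  dQ <- matrix(0, nrow(cc$Q), ncol(cc$Q)); dK <- dQ; dV <- dQ
  for (r in seq_len(cc$Tn)) {
    rows_q <- ((r - 1L) * n + 1L):(r * n)
    rows_kv <- cc$sel[[r]]
    A <- cc$A[[r]]
    dOr <- dO[rows_q, , drop = FALSE]
    dA <- tcrossprod(dOr, cc$V[rows_kv, , drop = FALSE])
    dV[rows_kv, ] <- dV[rows_kv, ] + crossprod(A, dOr)
    dS <- A * (dA - rowSums(dA * A))
    dQ[rows_q, ] <- dQ[rows_q, ] + dS %*% cc$K[rows_kv, , drop = FALSE] / cc$scale
    dK[rows_kv, ] <- dK[rows_kv, ] + crossprod(dS, cc$Q[rows_q, , drop = FALSE]) / cc$scale
  }
  list(dQ = dQ, dK = dK, dV = dV)
}
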