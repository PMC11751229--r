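# SP block: close-set head, one-vs-rest multi-binary head, superclass
# distribution / pseudo-label algebra, and the (K+1)-way open-set head.
#
# Class labels are 0-based throughout the public interface (in-distribution
# classes 0..K-1; the out-of-distribution superclass index is K), matching
# the convention of the image-folder datasets.

sp_heads_init <- function(E, K, seed = 1L) {
  with_seed(seed, {
    sd <- 1 / sqrt(E)
    structure(list(
      K = as.integer(K),
      close = list(W = matrix(rnorm(K * E, sd = sd), K, E), b = numeric(K)),
      multi = list(W = matrix(rnorm(2 * K * E, sd = sd), 2 * K, E),
                   b = numeric(2 * K)),
      open = list(W = matrix(rnorm((K + 1) * E, sd = sd), K + 1, E),
                  b = numeric(K + 1))
    ), class = "spemix_heads")
  })
}

as_row_embedding <- function(embedding) {
  if (is.null(dim(embedding))) matrix(embedding, nrow = 1L) else embedding
}

drop_single <- function(x, single) if (single) drop(x) else x

#' Close-set class probabilities
#'
#' Softmax over the K in-distribution view classes from a plain fully
#' connected layer on the encoder embedding.
#'
#' @param embedding length-`E` vector (one sample) or `n x E` matrix
#'   (samples in rows).
#' @param heads a `spemix_heads` bundle (see [spemix()] fits, element
#'   `student$heads`).
#' @return probability vector of length `K`, or `n x K` matrix.
#' @export
close_set_probs <- function(embedding, heads) {
  single <- is.null(dim(embedding))
  e <- as_row_embedding(embedding)
  drop_single(softmax_rows(e %*% t(heads$close$W) +
                             matrix(heads$close$b, nrow(e), heads$K, byrow = TRUE)),
              single)
}

#' Multi-binary (one-vs-rest) probabilities
#'
#' K independent two-way softmax heads; row `k` is `(q_k, 1 - q_k)` where
#' `q_k` is the probability that the sample belongs to in-distribution
#' class `k`.
#'
#' @inheritParams close_set_probs
#' @return `K x 2` matrix, or `n x K x 2` array for a batch.
#' @export
multi_binary_probs <- function(embedding, heads) {
  single <- is.null(dim(embedding))
  e <- as_row_embedding(embedding)
  K <- heads$K
  logits <- e %*% t(heads$multi$W) +
    matrix(heads$multi$b, nrow(e), 2 * K, byrow = TRUE)
  Q <- array(0, c(nrow(e), K, 2L))
  for (k in seq_len(K)) {
    lk <- logits[, c(2L * k - 1L, 2L * k), drop = FALSE]
    Q[, k, ] <- softmax_rows(lk)
  }
  if (single) array(Q[1L, , ], c(K, 2L)) else Q
}

#' Open-set (K+1)-way probabilities
#'
#' Softmax over the K in-distribution classes plus the out-of-distribution
#' superclass; applied to mixed unlabeled images during training.
#'
#' @inheritParams close_set_probs
#' @return probability vector of length `K + 1`, or `n x (K+1)` matrix.
#' @export
open_set_probs <- function(embedding, heads) {
  single <- is.null(dim(embedding))
  e <- as_row_embedding(embedding)
  drop_single(softmax_rows(e %*% t(heads$open$W) +
                             matrix(heads$open$b, nrow(e), heads$K + 1L, byrow = TRUE)),
              single)
}

as_PQ_batch <- function(P, Q) {
  if (is.null(dim(P))) {
    stopifnot(is.matrix(Q), ncol(Q) == 2L, nrow(Q) == length(P))
    P <- matrix(P, 1L)
    Q <- array(Q, c(1L, dim(Q)))
  } else if (length(dim(Q)) == 3L) {
    stopifnot(nrow(P) == dim(Q)[1], ncol(P) == dim(Q)[2], dim(Q)[3] == 2L)
  } else {
    stop("`Q` must be K x 2 for one sample or n x K x 2 for a batch")
  }
  list(P = P, Q = Q)
}

#' Superclass probability distribution
#'
#' Combines the close-set distribution `P` with the one-vs-rest matrix `Q`
#' into the two-way superclass distribution `Dp = (D_in, D_out)`:
#' `D_in = sum_k p_k q_k`, `D_out = sum_k p_k (1 - q_k)`. Because `P` lies
#' on the simplex and every row of `Q` sums to one, `D_in + D_out = 1`.
#'
#' @param P close-set probabilities, length-`K` vector or `n x K` matrix.
#' @param Q one-vs-rest probabilities, `K x 2` matrix or `n x K x 2` array.
#' @return `(D_in, D_out)` vector, or `n x 2` matrix for a batch.
#' @export
superclass_distribution <- function(P, Q) {
  single <- is.null(dim(P))
  pq <- as_PQ_batch(P, Q)
  din <- rowSums(pq$P * array(pq$Q[, , 1L], dim(pq$P)))
  dout <- rowSums(pq$P * array(pq$Q[, , 2L], dim(pq$P)))
  out <- cbind(D_in = din, D_out = dout)
  drop_single(out, single)
}

#' Superclass pseudo-label
#'
#' Splits the in-distribution superclass mass `D_in` over the K classes
#' with weights `alpha_i = p_i / sum(p)` and appends `D_out`, giving the
#' `(K+1)`-way superclass pseudo-label
#' `SP = (alpha_1 D_in, ..., alpha_K D_in, D_out)`. The hard pseudo-label
#' `y_sp` is the 0-based argmax of `SP` (`K` denotes the
#' out-of-distribution superclass); ties break toward the lowest index.
#'
#' @inheritParams superclass_distribution
#' @return list with `SP` (vector of length `K+1` or `n x (K+1)` matrix)
#'   and `y_sp` (0-based integer label(s) in `0..K`).
#' @export
superclass_pseudo_label <- function(P, Q) {
  single <- is.null(dim(P))
  pq <- as_PQ_batch(P, Q)
  psum <- rowSums(pq$P)
  if (any(psum <= 0)) {
    stop("all-zero close-set probability vector: cannot normalize the weight matrix")
  }
  Dp <- superclass_distribution(pq$P, pq$Q)
  if (is.null(dim(Dp))) Dp <- matrix(Dp, 1L)
  WM <- pq$P / psum
  SP <- cbind(WM * Dp[, 1L], Dp[, 2L])
  colnames(SP) <- NULL
  y_sp <- max.col(SP, ties.method = "first") - 1L
  list(SP = drop_single(SP, single), y_sp = drop_single(y_sp, single))
}
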