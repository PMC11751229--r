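# Loss terms. All losses operate on probabilities (training computes the
# matching gradients at the logits internally). Logs are clamped at
# LOG_EPS so confident heads never produce -Inf.

LOG_EPS <- 1e-8

check_simplex <- function(x, name, tol = 1e-4) {
  x <- if (is.null(dim(x))) matrix(x, 1L) else x
  if (any(x < -tol) || any(abs(rowSums(x) - 1) > tol)) {
    stop(sprintf("`%s` rows must be probability vectors (nonnegative, sum 1)", name))
  }
  x
}

#' Soft cross-entropy between probability vectors
#'
#' `-sum(target * log(pred))` with epsilon-clamped logarithms; equals the
#' Shannon entropy of `target` when `pred == target`.
#'
#' @param target,pred probability vectors of equal length, or matrices with
#'   one distribution per row (the mean row loss is returned).
#' @return nonnegative scalar.
#' @export
soft_cross_entropy <- function(target, pred) {
  t_ <- check_simplex(target, "target")
  p_ <- check_simplex(pred, "pred")
  stopifnot(identical(dim(t_), dim(p_)))
  mean(rowSums(-t_ * log(pmax(p_, LOG_EPS))))
}

one_hot <- function(y, K) {
  y <- as.integer(y)
  if (any(y < 0L) || any(y >= K)) {
    stop(sprintf("labels must lie in 0..%d", K - 1L))
  }
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Mask-generation loss
#'
#' Mixed soft cross-entropy anchoring the prediction on the mixed image to
#' the pre-mix predictions of its two sources:
#' `l_gen = lambda * ce(p1, p_mix) + (1 - lambda) * ce(p2, p_mix)`.
#' `p1`, `p2` are detached soft targets (teacher close-set predictions on
#' the un-mixed pair); during training the gradient flows only through
#' `p_mix`, hence into the mask generator via the mixed image.
#'
#' @param p1,p2 close-set probabilities of the un-mixed pair (vectors or
#'   matrices with samples in rows).
#' @param p_mix close-set probabilities on the mixed image.
#' @param lambda mixing ratio in (0, 1) (endpoints allowed for the
#'   degenerate single-source case).
#' @return nonnegative scalar.
#' @export
gen_loss <- function(p1, p2, p_mix, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  lambda * soft_cross_entropy(p1, p_mix) +
    (1 - lambda) * soft_cross_entropy(p2, p_mix)
}

#' DAMix loss
#'
#' Sum of the mask-generation loss and the labeled cross-entropy that
#' stabilizes mask learning early in training:
#' `l_DAMix = l_gen + ce(one_hot(y), labeled_pred)`.
#'
#' @param gen the [gen_loss()] value.
#' @param labeled_pred close-set probabilities on the labeled batch
#'   (vector or matrix, samples in rows).
#' @param y 0-based integer label(s).
#' @return scalar `l_DAMix`.
#' @export
damix_loss <- function(gen, labeled_pred, y) {
  p <- if (is.null(dim(labeled_pred))) matrix(labeled_pred, 1L) else labeled_pred
  gen + soft_cross_entropy(one_hot(y, ncol(p)), p)
}

#' Multi-binary loss with hard-negative sampling
#'
#' Per labeled sample, penalizes the true one-vs-rest head and the hardest
#' negative head only: `-log q_y - log(1 - q_k*)` where
#' `k* = argmin_{k != y} log(1 - q_k)` (equivalently the non-true class
#' with the largest `q_k`); the batch mean is returned.
#'
#' @param Q_batch one-vs-rest probabilities, `K x 2` (single sample) or
#'   `B x K x 2` array.
#' @param labels 0-based integer labels, `< K`.
#' @return nonnegative scalar.
#' @export
multi_binary_loss <- function(Q_batch, labels) {
  if (length(dim(Q_batch)) == 2L) Q_batch <- array(Q_batch, c(1L, dim(Q_batch)))
  B <- dim(Q_batch)[1]; K <- dim(Q_batch)[2]
  if (K < 2L) stop("multi-binary loss needs K >= 2 (no negative class exists)")
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= K)) {
    stop(sprintf("labels must lie in 0..%d", K - 1L))
  }
  total <- 0
  for (i in seq_len(B)) {
    q <- Q_batch[i, , 1L]
    y <- labels[i] + 1L
    neg <- setdiff(seq_len(K), y)
    kstar <- neg[which.max(q[neg])]
    total <- total - log(pmax(q[y], LOG_EPS)) -
      log(pmax(1 - q[kstar], LOG_EPS))
  }
  total / B
}

#' SP block supervised loss
#'
#' `l_SP = l_close + l_mul`: the close-set cross-entropy on the labeled
#' batch plus the multi-binary hard-negative loss.
#'
#' @param close_pred close-set probabilities on the labeled batch.
#' @param y 0-based labels for `close_pred`.
#' @param Q_batch,labels arguments of [multi_binary_loss()].
#' @return scalar `l_SP`.
#' @export
sp_loss <- function(close_pred, y, Q_batch, labels) {
  p <- if (is.null(dim(close_pred))) matrix(close_pred, 1L) else close_pred
  soft_cross_entropy(one_hot(y, ncol(p)), p) + multi_binary_loss(Q_batch, labels)
}

#' Open-set loss on mixed unlabeled images
#'
#' Hard superclass pseudo-labels of the two sources, mixed with the same
#' ratio as the images:
#' `l_op = lambda * ce(one_hot(y_sp_u1), o_mix) + (1 - lambda) *
#' ce(one_hot(y_sp_u2), o_mix)` with `y_sp = argmax(SP)`.
#'
#' @param SP_u1,SP_u2 superclass pseudo-label distributions of the un-mixed
#'   pair (length `K+1` vectors or matrices with samples in rows).
#' @param o_mix open-set probabilities on the mixed image.
#' @param lambda the mixing ratio used to build the mixed image.
#' @return nonnegative scalar.
#' @export
open_set_loss <- function(SP_u1, SP_u2, o_mix, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  s1 <- if (is.null(dim(SP_u1))) matrix(SP_u1, 1L) else SP_u1
  s2 <- if (is.null(dim(SP_u2))) matrix(SP_u2, 1L) else SP_u2
  o <- if (is.null(dim(o_mix))) matrix(o_mix, 1L) else o_mix
  Kp1 <- ncol(o)
  y1 <- max.col(s1, ties.method = "first") - 1L
  y2 <- max.col(s2, ties.method = "first") - 1L
  lambda * soft_cross_entropy(one_hot(y1, Kp1), o) +
    (1 - lambda) * soft_cross_entropy(one_hot(y2, Kp1), o)
}

#' Total training loss
#'
#' Unweighted sum `l_total = l_DAMix + l_SP + l_op`.
#'
#' @param terms named list (or `loss_terms` record) with elements `damix`,
#'   `sp`, `op`.
#' @return scalar.
#' @export
total_loss <- function(terms) {
  terms$damix + terms$sp + terms$op
}
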