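# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

# image batches are stored as (C, H, W, B) arrays internally; the public
# interface uses (H, W, B) grayscale arrays (or H x W matrices).
as_chwb <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (length(d) == 4L) return(x)
  if (length(d) != 3L) stop("expected an H x W matrix or H x W x B array of images")
  out <- array(0, c(1L, d[1], d[2], d[3]))
  out[1, , , ] <- x
  out
}

from_chwb <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[1] == 1L)
  array(x[1, , , ], d[2:4])
}

# row-wise softmax of a matrix of logits
softmax_rows <- function(z) {
  e <- exp(z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))])
  e / rowSums(e)
}

clamp01 <- function(x, eps = 1e-8) pmin(pmax(x, eps), 1 - eps)
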