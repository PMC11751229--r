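# S3 methods for fitted models, plus checkpoint helpers.

# batched inference on raw images; returns 0-based class, P, Dp
predict_state <- function(state, images, batch_size = 256L) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  B <- dim(images)[3]
  K <- state$K
  P <- matrix(0, B, K)
  Dp <- matrix(0, B, 2L)
  i <- 1L
  while (i <= B) {
    j <- min(i + batch_size - 1L, B)
    si <- student_infer(state, images[, , i:j, drop = FALSE])
    P[i:j, ] <- si$P
    Q <- array(0, c(j - i + 1L, K, 2L))
    Q[, , 1L] <- si$q; Q[, , 2L] <- 1 - si$q
    dp <- superclass_distribution(si$P, Q)
    if (is.null(dim(dp))) dp <- matrix(dp, 1L)
    Dp[i:j, ] <- dp
    i <- j + 1L
  }
  colnames(Dp) <- c("D_in", "D_out")
  list(class = max.col(P, ties.method = "first") - 1L, P = P, Dp = Dp)
}

#' Predict view classes for new images
#'
#' Inference uses the student close-set head; the predicted class is the
#' argmax of the close-set probabilities (ties break toward the lowest
#' class index). `Dp` reports the superclass distribution; its `D_out`
#' column is the model's out-of-distribution score.
#'
#' @param object a [spemix()] fit.
#' @param newdata `H x W` matrix or `H x W x B` array of images in
#'   [0, 1], or a `synth_dataset` (its test split is used).
#' @param type `"class"` (0-based integer predictions), `"prob"` (close-set
#'   probability matrix), or `"all"` (list with `class`, `P`, `Dp`).
#' @param ... unused.
#' @export
predict.spemix <- function(object, newdata, type = c("class", "prob", "all"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "synth_dataset")) newdata <- newdata$test$images
  pr <- predict_state(object$state, newdata)
  switch(type, class = pr$class, prob = pr$P, all = pr)
}

#' @export
print.spemix <- function(x, ...) {
  cat(sprintf("Open-set semi-supervised view classifier (mode: %s)\n",
              x$loss_mode))
  cat(sprintf("  classes: %s (+ OOD superclass)\n",
              paste(x$class_names, collapse = ", ")))
  cat(sprintf("  encoder widths: %s | parameters: %s\n",
              paste(x$config$encoder$stage_widths, collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  steps trained: %d\n", x$state$step))
  if (nrow(x$history)) {
    va <- x$history$val_acc
    va <- va[!is.na(va)]
    if (length(va)) cat(sprintf("  final test accuracy: %.3f\n", va[length(va)]))
  }
  invisible(x)
}

#' @export
summary.spemix <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nLast epochs:\n")
    print(utils::tail(object$history[, c("epoch", "gen", "labeled", "mul",
                                         "close", "op", "total", "val_acc")],
                      5L), row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Plot training history
#'
#' Loss-term trajectories and (when recorded) test accuracy by epoch.
#'
#' @param x a [spemix()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spemix <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  cols <- c(gen = "tan3", close = "steelblue", mul = "seagreen",
            op = "orchid4", total = "black")
  matplot(h$epoch, h[, names(cols)], type = "l", lty = 1, col = cols,
          xlab = "epoch", ylab = "loss", main = "loss terms", ...)
  legend("topright", legend = names(cols), col = cols, lty = 1, bty = "n")
  va <- h$val_acc
  plot(h$epoch, va, type = "b", pch = 16, xlab = "epoch", ylab = "accuracy",
       main = "test accuracy", ylim = c(0, 1))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoints containing the configurations, all parameter
#' arrays, normalization statistics, optimizer state and step counter.
#'
#' @param object a [spemix()] fit.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "spemix"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "spemix"))
  obj
}
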