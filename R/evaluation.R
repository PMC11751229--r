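# Evaluation: row-normalized confusion matrix, one-vs-rest ROC/AUC, and
# the full metrics report (with OOD AUROC from D_out on synthetic data).

#' Row-normalized confusion matrix
#'
#' Entry `(i, j)` is the fraction of class-`i` samples predicted as class
#' `j`; the diagonal is the per-class accuracy. Rows of classes with no
#' samples are `NaN` (with a warning).
#'
#' @param y_true,y_pred 0-based integer labels, `< K`.
#' @param K number of classes.
#' @return `K x K` matrix with rows summing to 1.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= K)) {
    stop(sprintf("labels must lie in 0..%d", K - 1L))
  }
  cm <- matrix(0, K, K)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1
  }
  rs <- rowSums(cm)
  if (any(rs == 0)) warning("some true classes have no samples; NaN rows")
  cm / rs
}

#' ROC points by threshold sweep
#'
#' Sweeps the unique score values as thresholds (plus the endpoints) and
#' reports (FPR, TPR) pairs; always includes (0, 0) and (1, 1).
#'
#' @param scores real-valued scores, larger = more positive.
#' @param labels binary labels (0/1 or logical).
#' @return data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ROC curve")
  }
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn, 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
             threshold = c(Inf, thr, -Inf))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over the threshold-sweep ROC; ties in the
#' scores receive half credit, so the value equals the Mann-Whitney
#' probability that a random positive outranks a random negative.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' Evaluate a fitted model
#'
#' Computes the metrics report on a test split: row-normalized confusion
#' matrix, per-class and overall accuracy, one-vs-rest AUC per class (the
#' close-set probability column is the score), the trainable parameter
#' count, and — when hidden out-of-distribution labels are supplied
#' (synthetic data only) — the AUROC of `D_out` as an OOD score.
#'
#' @param object a [spemix()] fit.
#' @param test list with `images` and 0-based `labels`, or a
#'   `synth_dataset` (its test split is used).
#' @param ood_images,ood_hidden_labels optional images with hidden labels
#'   (`>= K` marking out-of-distribution) for OOD scoring.
#' @param export_dir optional directory; writes `metrics.json`,
#'   `confusion.csv` and per-class `roc_<class>.csv` files.
#' @return list of class `spemix_metrics`.
#' @export
evaluate <- function(object, test, ood_images = NULL,
                     ood_hidden_labels = NULL, export_dir = NULL) {
  stopifnot(inherits(object, "spemix"))
  if (inherits(test, "synth_dataset")) {
    if (is.null(ood_images) && !all(is.na(test$unlabeled$hidden_labels))) {
      ood_images <- test$unlabeled$images
      ood_hidden_labels <- test$unlabeled$hidden_labels
    }
    test <- test$test
  }
  if (length(test$labels) == 0L) stop("test set is empty")
  K <- object$K
  pr <- predict_state(object$state, test$images)
  cm <- confusion_matrix(test$labels, pr$class, K)
  dimnames(cm) <- list(true = object$class_names, pred = object$class_names)
  auc <- vapply(seq_len(K), function(k) {
    roc_auc(pr$P[, k], test$labels == (k - 1L))
  }, 0)
  names(auc) <- object$class_names
  ood_auroc <- NA_real_
  if (!is.null(ood_images) && !is.null(ood_hidden_labels)) {
    po <- predict_state(object$state, ood_images)
    ood_auroc <- roc_auc(po$Dp[, "D_out"], ood_hidden_labels >= K)
  }
  rep_ <- structure(list(
    confusion = cm,
    per_class_accuracy = diag(cm),
    overall_accuracy = mean(pr$class == test$labels),
    auc = auc,
    ood_auroc = ood_auroc,
    n_parameters = count_parameters(object)
  ), class = "spemix_metrics")
  if (!is.null(export_dir)) {
    dir.create(export_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cm, file.path(export_dir, "confusion.csv"))
    for (k in seq_len(K)) {
      pts <- roc_points(pr$P[, k], test$labels == (k - 1L))
      write.csv(pts, file.path(export_dir,
                               sprintf("roc_%s.csv", object$class_names[k])),
                row.names = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(list(
        overall_accuracy = rep_$overall_accuracy,
        per_class_accuracy = as.list(rep_$per_class_accuracy),
        auc = as.list(rep_$auc), ood_auroc = rep_$ood_auroc,
        n_parameters = rep_$n_parameters),
        file.path(export_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  rep_
}

#' @export
print.spemix_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  cat("Per-class accuracy:\n")
  print(round(x$per_class_accuracy, 4))
  cat("One-vs-rest AUC:\n")
  print(round(x$auc, 4))
  if (!is.na(x$ood_auroc)) cat(sprintf("OOD AUROC (D_out): %.4f\n", x$ood_auroc))
  cat(sprintf("Trainable parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  invisible(x)
}
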