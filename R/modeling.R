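#' Principal component analysis of selected-variable intensities
#'
#' Eigendecomposition of the correlation matrix (`scaling_mode =
#' "autoscale"`, the default) or covariance matrix (`"center"`) of the
#' samples-by-variables intensity matrix, through [stats::prcomp()].
#' Loadings follow a fixed sign convention — each component's
#' largest-magnitude loading is positive — so reports are reproducible
#' run to run.
#'
#' @param x Numeric matrix, samples in rows, variables in columns
#'   (>= 2 samples, >= 1 variable).
#' @param scaling_mode `"autoscale"` (correlation) or `"center"`
#'   (covariance).
#' @return An object of class `ssir_pca`: list with `variable_ids`,
#'   `center`, `scale`, `loadings` (variables x components, orthonormal),
#'   `sdev` and `explained_fraction`.
#' @export
pca_fit <- function(x, scaling_mode = c("autoscale", "center")) {
  scaling_mode <- match.arg(scaling_mode)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  if (ncol(x) < 1L) stop("PCA needs at least 1 variable")
  if (scaling_mode == "autoscale") {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant variable under autoscale: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scaling_mode == "autoscale")
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(variable_ids = colnames(x), center = pc$center,
         scale = if (scaling_mode == "autoscale") pc$scale
                 else rep(1, ncol(x)),
         scaling_mode = scaling_mode, loadings = rot, sdev = pc$sdev,
         explained_fraction = pc$sdev^2 / sum(pc$sdev^2)),
    class = "ssir_pca")
}

#' @export
print.ssir_pca <- function(x, ...) {
  cat(sprintf("<ssir_pca> %d variable(s), %d component(s) (%s)\n",
              length(x$center), ncol(x$loadings), x$scaling_mode))
  ef <- round(100 * x$explained_fraction, 1)
  cat("  explained variance (%):", paste(ef, collapse = ", "), "\n")
  invisible(x)
}

#' Project samples onto fitted principal components
#'
#' @param model An `ssir_pca`.
#' @param x Samples-by-variables matrix over the model's variables.
#' @return Samples-by-components score matrix.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "ssir_pca"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("variable mismatch: model has ", length(model$center),
         " variables, data has ", ncol(x))
  if (!is.null(model$variable_ids) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$variable_ids))
    stop("variable names do not match the fitted model")
  scale(x, center = model$center, scale = model$scale) %*% model$loadings
}

#' Fisher linear discriminant on leading principal components
#'
#' Fits the Fisher direction `w = S_pooled^{-1} (mean_1 - mean_0)` on
#' the first `k` score columns with the midpoint decision threshold
#' `w . (mean_1 + mean_0) / 2`; a sample is assigned the positive class
#' iff `w . s >= threshold`. For `k = 1` this reduces to a midpoint cut
#' on the first component.
#'
#' @param scores Samples-by-components score matrix.
#' @param labels 0/1 class labels, both classes present.
#' @param k Number of leading components to use.
#' @return An object of class `ssir_lda`: list with `k`, `w`,
#'   `threshold`, `positive_class = 1`.
#' @export
discriminant_fit <- function(scores, labels, k = 1) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) stop("labels/scores length mismatch")
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) != 2L)
    stop("both classes (0 and 1) must be present")
  if (k < 1 || k > ncol(scores))
    stop("'k' must lie in 1..", ncol(scores))
  s <- scores[, seq_len(k), drop = FALSE]
  m1 <- colMeans(s[labels == 1L, , drop = FALSE])
  m0 <- colMeans(s[labels == 0L, , drop = FALSE])
  if (isTRUE(all.equal(m1, m0, tolerance = 1e-12)))
    stop("class means coincide; discriminant direction is degenerate")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  cv <- function(m) if (nrow(m) > 1L) stats::cov(m) else
    matrix(0, ncol(m), ncol(m))
  sp <- ((n1 - 1) * cv(s[labels == 1L, , drop = FALSE]) +
         (n0 - 1) * cv(s[labels == 0L, , drop = FALSE])) / (n1 + n0 - 2)
  w <- tryCatch(solve(sp, m1 - m0),
                error = function(e)
                  stop("pooled covariance is singular; try a smaller k (",
                       conditionMessage(e), ")"))
  structure(list(k = as.integer(k), w = as.numeric(w),
                 threshold = sum(w * (m1 + m0)) / 2, positive_class = 1L),
            class = "ssir_lda")
}

#' @export
print.ssir_lda <- function(x, ...) {
  cat(sprintf("<ssir_lda> %d component(s); threshold %.4g\n",
              x$k, x$threshold))
  invisible(x)
}

#' @export
predict.ssir_lda <- function(object, newdata, ...) {
  s <- as.matrix(newdata)
  if (ncol(s) < object$k) stop("scores have fewer than k columns")
  as.integer(s[, seq_len(object$k), drop = FALSE] %*% object$w >=
             object$threshold)
}

#' Classification metrics against true labels
#'
#' Class 1 is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param predictions,labels Equal-length 0/1 vectors.
#' @return An object of class `ssir_metrics`: list with confusion
#'   counts `tp`, `fp`, `tn`, `fn` and `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
evaluate_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("'predictions' and 'labels' must have equal length")
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("unseen label value: predictions and labels must be 0/1")
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(labels)),
            class = "ssir_metrics")
}

#' @export
print.ssir_metrics <- function(x, ...) {
  cat(sprintf(paste0("<ssir_metrics> sensitivity %.1f%%, specificity ",
                     "%.1f%%, accuracy %.1f%% (TP %d, FP %d, TN %d, FN %d)\n"),
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
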