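#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise-concordance statistic via midranks:
#' the probability that a random positive ("good") voxel scores above a
#' random negative one, with tied scores credited 0.5.
#'
#' @param labels Binary labels: `"good"`/`"bad"`, or 0/1 (1 = positive), or
#'   logical.
#' @param scores Numeric scores, higher = more "good".
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC-AUC needs both classes present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-convention average precision on the positive ("good") class: scores
#' are processed in descending order, tied scores as one threshold group,
#' and each group contributes its new true positives times the precision at
#' that threshold. No trapezoidal PR interpolation is applied.
#'
#' @inheritParams roc_auc
#' @return AUC-PR in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("AUC-PR needs at least one positive-class voxel")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  groups <- cumsum(!duplicated(s))
  tp_g <- tapply(y, groups, sum)
  n_g <- tapply(y, groups, length)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  sum(tp_g * (tp_cum / n_cum)) / n_pos
}

#' Thresholded classification accuracy
#'
#' Fraction of voxels whose thresholded positive-class score matches the
#' label. At the default threshold 0.5 this coincides with argmax on a
#' two-class softmax.
#'
#' @inheritParams roc_auc
#' @param threshold Scores strictly above it predict "good".
#' @return Accuracy in \[0, 1\].
#' @export
qc_accuracy <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(y) == 0L) stop("accuracy of an empty set is undefined")
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  mean((scores > threshold) == (y == 1L))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("good", "bad")))
      stop("character labels must be \"good\"/\"bad\"")
    as.integer(labels == "good")
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' Metrics report for a set of voxels
#'
#' Computes ROC-AUC, AUC-PR and accuracy for the voxels selected by `mask`.
#' On a single-class subset the AUC-based metrics are undefined and reported
#' as `NA` (with a warning); accuracy is still computed.
#'
#' @inheritParams roc_auc
#' @param mask Logical per-voxel inclusion mask (default: all voxels).
#' @param threshold Accuracy threshold, see [qc_accuracy()].
#' @param subset_tag Label recorded in the report (`"all"`,
#'   `"lesion_only"`, ...).
#' @return An object of class `metrics_report` with fields `auc`, `auc_pr`,
#'   `accuracy`, `n_voxels`, `subset_tag`.
#' @export
subset_report <- function(labels, scores, mask = NULL, threshold = 0.5,
                          subset_tag = if (is.null(mask)) "all" else "subset") {
  if (is.null(mask)) mask <- rep(TRUE, length(labels))
  if (!is.logical(mask) || length(mask) != length(labels))
    stop("mask must be a logical vector matching the voxel count")
  if (!any(mask)) stop("empty voxel subset")
  l <- labels[mask]; s <- scores[mask]
  auc <- tryCatch(roc_auc(l, s), error = function(e) {
    warning("ROC-AUC undefined on this subset: ", conditionMessage(e))
    NA_real_
  })
  ap <- tryCatch(pr_auc(l, s), error = function(e) {
    warning("AUC-PR undefined on this subset: ", conditionMessage(e))
    NA_real_
  })
  structure(list(auc = auc, auc_pr = ap,
                 accuracy = qc_accuracy(l, s, threshold),
                 n_voxels = sum(mask), subset_tag = subset_tag),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (n = %d): AUC %.3f, AUC-PR %.3f, accuracy %.3f\n",
              x$subset_tag, x$n_voxels, x$auc, x$auc_pr, x$accuracy))
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Mean and sample (n-1) standard deviation of each metric across folds,
#' in the conventional "mean +/- sd" layout. A single fold reports sd 0 by
#' convention.
#'
#' @param reports List of `metrics_report`s.
#' @return An object of class `metrics_aggregate`: per-metric `mean` and
#'   `sd` vectors.
#' @export
aggregate_folds <- function(reports) {
  if (!length(reports)) stop("no fold reports to aggregate")
  stopifnot(all(vapply(reports, inherits, logical(1L), "metrics_report")))
  metrics <- c("auc", "auc_pr", "accuracy")
  m <- sapply(metrics, function(nm)
    vapply(reports, function(r) r[[nm]], numeric(1L)))
  m <- matrix(m, nrow = length(reports),
              dimnames = list(NULL, metrics))
  means <- colMeans(m, na.rm = TRUE)
  sds <- apply(m, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) 0 else stats::sd(col)
  })
  structure(list(mean = means, sd = sds, n_folds = length(reports)),
            class = "metrics_aggregate")
}

#' @export
print.metrics_aggregate <- function(x, ...) {
  cat(sprintf("Aggregate over %d fold(s):\n", x$n_folds))
  for (nm in names(x$mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}
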