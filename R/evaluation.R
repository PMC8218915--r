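# Classification metrics, ROC / precision-recall curves, and Euclidean
# distance clustering for heatmap ordering.

#' Confusion-matrix counts and derived metrics
#'
#' Counts TP/TN/FP/FN from binary truth and predictions and derives
#' ACC = (TP+TN)/(TP+TN+FP+FN), F1 = 2TP/(2TP+FP+FN) and
#' PRE = TP/(TP+FP). Precision is `NA` when no positive prediction was
#' made (TP+FP = 0); F1 is 0 when its denominator vanishes.
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return List with `tp`, `tn`, `fp`, `fn`, `acc`, `f1`, `pre`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("truth and prediction differ in length")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  tp <- sum(y_pred == 1L & y_true == 1L)
  tn <- sum(y_pred == 0L & y_true == 0L)
  fp <- sum(y_pred == 1L & y_true == 0L)
  fn <- sum(y_pred == 0L & y_true == 1L)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       acc = (tp + tn) / length(y_true),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       pre = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

#' ROC curve, AUC and Gini index
#'
#' Sweeps the threshold over the descending unique scores (a sample is
#' called positive when its score >= threshold; tied scores form a single
#' threshold), always including the (0,0) and (1,1) endpoints, and
#' integrates the curve by the trapezoidal rule. The Gini index is
#' `2 * auc - 1`. With ties handled this way the AUC equals the
#' Mann-Whitney concordant-pair fraction (ties counted 1/2).
#'
#' @param y_true binary 0/1 truth; both classes present.
#' @param scores real-valued classifier scores, higher = more positive.
#' @return List with `points` (data frame `fpr`, `tpr`), `auc`, `gini`.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("truth and scores differ in length")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present in the truth")
  ord <- order(-scores)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative counts at each threshold boundary (last index of tied block)
  block_end <- which(c(diff(s) != 0, TRUE))
  tpr <- c(0, cumsum(y == 1L)[block_end] / n_pos)
  fpr <- c(0, cumsum(y == 0L)[block_end] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr),
       auc = auc, gini = 2 * auc - 1)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at each descending score threshold; the area is
#' the step-wise (average-precision) sum
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over thresholds.
#'
#' @inheritParams roc_curve
#' @return List with `points` (data frame `recall`, `precision`) and
#'   `auc_pr`.
#' @export
pr_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("truth and scores differ in length")
  n_pos <- sum(y_true == 1L)
  if (n_pos == 0L || all(y_true == 1L))
    stop("both classes must be present in the truth")
  ord <- order(-scores)
  y <- y_true[ord]
  s <- scores[ord]
  block_end <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(y == 1L)[block_end]
  called <- block_end
  recall <- tp / n_pos
  precision <- tp / called
  auc_pr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision),
       auc_pr = auc_pr)
}

#' Pairwise Euclidean distances between samples
#'
#' Standard metric \eqn{d(x, y) = \sqrt{\sum_j (x_j - y_j)^2}} between all
#' pairs of sample columns.
#'
#' @param mat an [expression_matrix()] or a plain numeric matrix with
#'   samples in columns.
#' @return Symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
euclidean_distance_matrix <- function(mat) {
  values <- if (inherits(mat, "ExpressionMatrix")) mat$values else as.matrix(mat)
  if (!all(is.finite(values))) stop("values must be finite")
  as.matrix(stats::dist(t(values), method = "euclidean"))
}

#' Leaf order of average-linkage clustering of a distance matrix
#'
#' Hierarchical clustering (average linkage) of the samples, returning the
#' dendrogram leaf order used to arrange heatmap rows/columns so that
#' similar samples are adjacent. Deterministic for a fixed input.
#'
#' @param dist_matrix symmetric non-negative matrix with zero diagonal.
#' @return Integer permutation of `1:n`.
#' @export
cluster_order <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (nrow(d) == 1L) return(1L)
  stats::hclust(stats::as.dist(d), method = "average")$order
}

#' Full evaluation report from truth and classifier scores
#'
#' Bundles the confusion-matrix metrics (at threshold `threshold` on the
#' scores), the ROC curve with AUC and Gini, and the precision-recall
#' curve; optionally a Euclidean distance matrix of the evaluated samples
#' for heatmap clustering.
#'
#' @param y_true binary 0/1 truth.
#' @param scores classifier probabilities/scores.
#' @param threshold classification threshold on scores (default 0.5).
#' @param mat optional [expression_matrix()] restricted to the evaluated
#'   features; when given, `distance_matrix` and `sample_order` are
#'   included.
#' @return An `EvaluationReport` list: confusion counts and metrics,
#'   `roc_points`, `auc`, `gini`, `pr_points`, `auc_pr`, and optionally
#'   `distance_matrix`, `sample_order`.
#' @export
evaluation_report <- function(y_true, scores, threshold = 0.5, mat = NULL) {
  cm <- confusion_metrics(y_true, as.integer(scores >= threshold))
  roc <- roc_curve(y_true, scores)
  pr <- pr_curve(y_true, scores)
  rep <- c(cm,
           list(roc_points = roc$points, auc = roc$auc, gini = roc$gini,
                pr_points = pr$points, auc_pr = pr$auc_pr))
  if (!is.null(mat)) {
    rep$distance_matrix <- euclidean_distance_matrix(mat)
    rep$sample_order <- cluster_order(rep$distance_matrix)
  }
  structure(rep, class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport\n")
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  ACC %.4f  F1 %.4f  PRE %s\n", x$acc, x$f1,
              ifelse(is.na(x$pre), "NA", sprintf("%.4f", x$pre))))
  cat(sprintf("  AUC %.4f  Gini %.4f  PR-AUC %.4f\n",
              x$auc, x$gini, x$auc_pr))
  invisible(x)
}

#' Write flat evaluation metrics as JSON
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  flat <- list(acc = report$acc, f1 = report$f1, pre = report$pre,
               auc = report$auc, gini = report$gini,
               auc_pr = report$auc_pr,
               counts = list(tp = report$tp, tn = report$tn,
                             fp = report$fp, fn = report$fn))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Cluster-ordered matrix for heatmap display
#'
#' Reorders the columns (samples) of a matrix by [cluster_order()] on
#' their Euclidean distances, writes the ordered matrix as TSV, and
#' optionally renders a PNG heatmap when the pheatmap package is
#' installed (the plot is a convenience; the ordered matrix is the
#' artifact).
#'
#' @param mat an [expression_matrix()].
#' @param tsv_path output TSV path for the ordered matrix.
#' @param png_path optional PNG path.
#' @return The column permutation, invisibly.
#' @export
export_heatmap <- function(mat, tsv_path, png_path = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  ord <- cluster_order(euclidean_distance_matrix(mat))
  ordered <- subset_samples(mat, ord)
  write_matrix(ordered, tsv_path)
  if (!is.null(png_path)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(png_path, width = 900, height = 700)
      pheatmap::pheatmap(ordered$values, cluster_rows = FALSE,
                         cluster_cols = FALSE)
      grDevices::dev.off()
    } else {
      warning("pheatmap not installed; PNG not written")
    }
  }
  invisible(ord)
}
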