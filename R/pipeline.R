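# The full two-stage pipeline: Fisher-score filter layer -> RFE/logistic
# embedded layer -> held-out-fold evaluation of the selected subset.

#' Pipeline configuration
#'
#' Collects every tunable of the two-stage pipeline with its default.
#'
#' @param target_dim exact size of the final selected subset; the RFE
#'   floor is set to it and the floor-sized step is returned. Default 78,
#'   the subset size at which classification on these data saturates.
#'   Set `NULL` to instead return the CV-accuracy-maximising step above
#'   `floor`.
#' @param floor smallest RFE subset size when `target_dim` is `NULL`.
#' @param k_folds cross-validation folds (default 4), stratified by class.
#' @param pace features dropped per RFE round; `NULL` (default) keys it to
#'   the post-filter dimension via [choose_pace()].
#' @param fisher_denominator `"within_class"` (default) or `"pooled"`,
#'   see [fisher_score()].
#' @param min_keep,max_keep clamp on the filter-layer inflection cut
#'   (defaults 50 and 4000). `min_keep` is raised to `target_dim` when
#'   necessary so the embedded layer always has enough features.
#' @param keep manual override of the filter cut (skips elbow detection).
#' @param learning_rate,max_iter,tol,lambda logistic training
#'   hyperparameters, see [logistic_hp()].
#' @return A list of class `frl_config`.
#' @export
frl_config <- function(target_dim = 78L, floor = 1L, k_folds = 4L,
                       pace = NULL,
                       fisher_denominator = c("within_class", "pooled"),
                       min_keep = 50L, max_keep = 4000L, keep = NULL,
                       learning_rate = 0.1, max_iter = 2000L, tol = 1e-7,
                       lambda = 0) {
  fisher_denominator <- match.arg(fisher_denominator)
  if (!is.null(target_dim) && target_dim < 1L)
    stop("target_dim must be >= 1 or NULL")
  structure(list(target_dim = target_dim, floor = as.integer(floor),
                 k_folds = as.integer(k_folds), pace = pace,
                 fisher_denominator = fisher_denominator,
                 min_keep = as.integer(min_keep),
                 max_keep = as.integer(max_keep), keep = keep,
                 hp = logistic_hp(learning_rate = learning_rate,
                                  max_iter = max_iter, tol = tol,
                                  lambda = lambda)),
            class = "frl_config")
}

#' Run the full two-stage feature-selection pipeline
#'
#' Chains the filter layer (Fisher-score ranking cut at the inflection
#' point, yielding the post-filter matrix A1 of dimension d1) and the
#' embedded layer (recursive feature elimination around the logistic
#' classifier under stratified K-fold cross-validation, yielding the
#' selected subset A2), then evaluates the selected subset from pooled
#' out-of-fold predictions: confusion metrics, ROC/AUC/Gini and
#' precision-recall, plus the Euclidean distance matrix of the samples on
#' the selected genes.
#'
#' When `config$target_dim` is set (default 78) the selected subset has
#' exactly that many genes; otherwise the CV-accuracy-maximising RFE step
#' is chosen.
#'
#' @param mat labelled [expression_matrix()], both classes present.
#' @param config an [frl_config()].
#' @param seed integer seed governing all randomness (fold assignment).
#' @return An `frl_result` list: `ranking` (FisherRanking), `path`
#'   (RfePath), `report` (EvaluationReport), `selected_features`,
#'   `config`, `seed`.
#' @export
run_frl <- function(mat, config = frl_config(), seed = 1L) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(config, "frl_config"))
  check_two_classes(mat)
  target <- config$target_dim
  min_keep <- config$min_keep
  if (!is.null(target)) {
    if (nrow(mat$values) < target)
      stop("matrix has ", nrow(mat$values),
           " genes, fewer than target_dim = ", target)
    min_keep <- max(min_keep, target)
  }
  ranking <- rank_genes(mat, denominator = config$fisher_denominator,
                        min_keep = min_keep, max_keep = config$max_keep,
                        keep = config$keep)
  a1 <- apply_filter(mat, ranking)
  floor <- if (is.null(target)) config$floor else as.integer(target)
  path <- rfe(a1, pace = config$pace, k = config$k_folds, floor = floor,
              hp = config$hp, seed = seed,
              select = if (is.null(target)) "best" else "floor")
  selected <- path$selected_features
  a2 <- expression_matrix(mat$values[selected, , drop = FALSE],
                          labels = mat$labels, scale = mat$scale)
  folds <- kfold_split(ncol(mat$values), mat$labels, k = config$k_folds,
                       seed = seed)
  fit <- cv_fit(a2$values, a2$labels, selected, folds, config$hp)
  report <- evaluation_report(mat$labels, fit$oof_prob, mat = a2)
  structure(list(ranking = ranking, path = path, report = report,
                 selected_features = selected, config = config,
                 seed = as.integer(seed)),
            class = "frl_result")
}

#' @export
print.frl_result <- function(x, ...) {
  cat("Two-stage feature selection result\n")
  cat(sprintf("  filter layer: %d genes scored, d1 = %d retained\n",
              length(x$ranking$gene_ids), x$ranking$d1))
  cat(sprintf("  embedded layer: pace %d, %d folds, %d genes selected\n",
              x$path$pace, x$path$k, length(x$selected_features)))
  cat(sprintf("  held-out folds: ACC %.4f  F1 %.4f  AUC %.4f  Gini %.4f\n",
              x$report$acc, x$report$f1, x$report$auc, x$report$gini))
  invisible(x)
}

#' Write the outputs of a pipeline run to a directory
#'
#' Writes `selected_features.tsv` (gene_id, rank), `rfe_path.tsv`
#' (per-step subset size and CV metrics), `scores.tsv` (full Fisher
#' ranking with kept flag) and `metrics.json`.
#'
#' @param result an `frl_result` from [run_frl()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frl_result <- function(result, dir) {
  stopifnot(inherits(result, "frl_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sel <- data.frame(gene_id = result$selected_features,
                    rank = seq_along(result$selected_features))
  utils::write.table(sel, file.path(dir, "selected_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$path$steps, file.path(dir, "rfe_path.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rk <- result$ranking
  scores <- data.frame(gene_id = rk$gene_ids, score = rk$scores,
                       rank = seq_along(rk$gene_ids),
                       kept = seq_along(rk$gene_ids) <= rk$d1)
  utils::write.table(scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metrics_json(result$report, file.path(dir, "metrics.json"))
  invisible(dir)
}
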