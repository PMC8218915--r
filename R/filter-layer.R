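# Filter layer: Fisher scoring, descending ranking, inflection-point cut.

# Guard constants for degenerate (zero-variance) genes: a vanishing
# denominator with a real between-class spread is scored as
# numerator / DENOM_EPS, capped at SCORE_CEILING so downstream sorting
# stays finite and stable.
DENOM_EPS <- 1e-12
SCORE_CEILING <- 1e12

#' Fisher score of a single gene
#'
#' Ratio of between-class spread to within-class variance,
#' \deqn{F = \frac{\sum_k n_k (\mu_k - \mu)^2}{\sum_k n_k \sigma_k^2},}
#' where \eqn{n_k}, \eqn{\mu_k} and \eqn{\sigma_k^2} are the size, mean and
#' population variance of class \eqn{k} and \eqn{\mu} the grand mean.
#' Higher scores mean stronger class separation. With
#' `denominator = "pooled"` the denominator is instead the single
#' population variance of the gene across all samples (the literal
#' one-shared-variance reading of the score).
#'
#' A gene that is constant within every class but differs between classes
#' has a vanishing denominator; its score is capped at `1e12`. A gene
#' constant across all samples scores 0.
#'
#' @param values numeric vector, one expression value per sample.
#' @param labels binary class labels (0/1 or any two levels), one per
#'   sample; both classes must be present.
#' @param denominator `"within_class"` (default) or `"pooled"`.
#' @return Non-negative finite scalar.
#' @examples
#' fisher_score(c(0, 2, 2, 4), c(0, 0, 1, 1))  # 1
#' @export
fisher_score <- function(values, labels,
                         denominator = c("within_class", "pooled")) {
  denominator <- match.arg(denominator)
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  if (!all(is.finite(values))) stop("values must be finite")
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("both classes must be present to compute a Fisher score")
  mu <- mean(values)
  num <- 0
  wcv <- 0
  for (k in classes) {
    v <- values[labels == k]
    nk <- length(v)
    muk <- mean(v)
    num <- num + nk * (muk - mu)^2
    wcv <- wcv + nk * mean((v - muk)^2)
  }
  den <- if (denominator == "within_class") wcv
         else mean((values - mu)^2)
  if (den < DENOM_EPS) {
    if (num < DENOM_EPS) return(0)
    return(min(num / DENOM_EPS, SCORE_CEILING))
  }
  num / den
}

# Vectorised Fisher scores over all rows of a genes x samples matrix;
# identical arithmetic to fisher_score(), one pass per class.
fisher_scores_matrix <- function(values, labels, denominator = "within_class") {
  classes <- unique(labels)
  n <- ncol(values)
  mu <- rowMeans(values)
  num <- rep(0, nrow(values))
  wcv <- rep(0, nrow(values))
  for (k in classes) {
    cols <- which(labels == k)
    nk <- length(cols)
    vk <- values[, cols, drop = FALSE]
    muk <- rowMeans(vk)
    num <- num + nk * (muk - mu)^2
    wcv <- wcv + nk * (rowMeans(vk * vk) - muk^2)
  }
  den <- if (denominator == "within_class") wcv
         else rowMeans(values * values) - mu^2
  out <- ifelse(den < DENOM_EPS,
                ifelse(num < DENOM_EPS, 0,
                       pmin(num / DENOM_EPS, SCORE_CEILING)),
                num / den)
  pmax(out, 0)  # clamp tiny negative values from cancellation
}

#' Detect the inflection (elbow) point of a descending score curve
#'
#' Both axes are min-max normalised to \[0, 1\] and the point of maximum
#' perpendicular distance from the curve to the chord joining its first
#' and last points is located. The returned value is the number of scores
#' strictly before that elbow point — the size of the retained head of the
#' ranking — clamped into `[min_keep, min(max_keep, length(scores))]`. A
#' flat or exactly linear curve has no elbow and yields `min_keep`.
#'
#' @param scores numeric vector sorted non-increasing.
#' @param min_keep smallest admissible cut (default 50).
#' @param max_keep largest admissible cut (default 4000).
#' @return Integer cut position in `[min_keep, min(max_keep, length(scores))]`.
#' @examples
#' detect_inflection(c(10, 1, 0.9, 0.8, 0.7), min_keep = 1)  # 1
#' @export
detect_inflection <- function(scores, min_keep = 50L, max_keep = 4000L) {
  L <- length(scores)
  if (L == 0L) stop("empty score vector")
  if (is.unsorted(rev(scores)))  # rev() of non-increasing is non-decreasing
    stop("scores must be sorted non-increasing")
  clamp <- function(i) max(min(i, max_keep, L), min(min_keep, L))
  if (L == 1L || scores[1L] == scores[L]) return(as.integer(clamp(1L)))
  x <- (seq_len(L) - 1) / (L - 1)
  y <- (scores - scores[L]) / (scores[1L] - scores[L])
  # distance from (x_i, y_i) to the chord through (0, 1) and (1, 0),
  # up to the constant chord length
  d <- abs((y[L] - y[1L]) * x - (x[L] - x[1L]) * y + x[L] * y[1L] - y[L] * x[1L])
  elbow <- which.max(d)
  if (d[elbow] <= 0) return(as.integer(clamp(1L)))
  as.integer(clamp(elbow - 1L))
}

#' Rank all genes by Fisher score and locate the filter cut
#'
#' Scores every gene of a labelled matrix, sorts in descending order
#' (ties broken by gene id, lexicographically, for full determinism) and
#' fills in the inflection-point cut that defines the post-filter
#' dimensionality d1.
#'
#' @param mat labelled [expression_matrix()] with both classes present.
#' @param denominator passed to [fisher_score()].
#' @param min_keep,max_keep passed to [detect_inflection()].
#' @param keep optional manual override of the cut: when given, the
#'   inflection rule is skipped and `d1 = min(keep, n_genes)`.
#' @return A `FisherRanking`: list with `gene_ids` (descending-score
#'   order), `scores` (aligned, non-increasing), `inflection_index` and
#'   `d1` (both equal to the number of retained genes).
#' @export
rank_genes <- function(mat, denominator = c("within_class", "pooled"),
                       min_keep = 50L, max_keep = 4000L, keep = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  check_two_classes(mat)
  ids <- gene_ids(mat)
  if (anyDuplicated(ids))
    stop("gene ids must be unique; collapse probes/duplicates first")
  scores <- fisher_scores_matrix(mat$values, mat$labels, denominator)
  ord <- order(-scores, ids, method = "radix")
  scores <- scores[ord]
  ids <- ids[ord]
  cut <- if (is.null(keep)) {
    detect_inflection(scores, min_keep = min_keep, max_keep = max_keep)
  } else {
    as.integer(max(1L, min(keep, length(ids))))
  }
  structure(list(gene_ids = ids, scores = unname(scores),
                 inflection_index = cut, d1 = cut),
            class = "FisherRanking")
}

#' @export
print.FisherRanking <- function(x, ...) {
  cat(sprintf("FisherRanking: %d genes scored, cut at d1 = %d\n",
              length(x$gene_ids), x$d1))
  cat(sprintf("  top score %.4g, score at cut %.4g\n",
              x$scores[1L], x$scores[x$d1]))
  invisible(x)
}

#' Restrict a matrix to the genes retained by the filter layer
#'
#' Returns the sub-matrix of the `d1` top-ranked genes, rows ordered as in
#' the ranking (the post-filter matrix, often called A1).
#'
#' @param mat the labelled matrix the ranking was derived from.
#' @param ranking a `FisherRanking` from [rank_genes()].
#' @return An [expression_matrix()] with `ranking$d1` rows.
#' @export
apply_filter <- function(mat, ranking) {
  stopifnot(inherits(mat, "ExpressionMatrix"),
            inherits(ranking, "FisherRanking"))
  if (!setequal(ranking$gene_ids, gene_ids(mat)) ||
      length(ranking$gene_ids) != nrow(mat$values))
    stop("ranking does not match the matrix: gene sets differ")
  top <- ranking$gene_ids[seq_len(ranking$d1)]
  expression_matrix(mat$values[top, , drop = FALSE],
                    labels = mat$labels, scale = mat$scale)
}
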