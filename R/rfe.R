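# Embedded layer: recursive feature elimination wrapped around the
# logistic classifier under stratified K-fold cross-validation.

# Evaluate thunk with a private RNG stream; the caller's .Random.seed is
# untouched, so library functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Elimination pace from the post-filter dimensionality
#'
#' The number of features dropped per elimination round is keyed to the
#' post-filter dimension d1: 5 when d1 > 2000, 3 when 1000 < d1 <= 2000,
#' 2 when d1 <= 1000. At the open boundaries the finer (slower) pace is
#' taken, i.e. exactly 2000 gives 3 and exactly 1000 gives 2.
#'
#' @param d1 integer post-filter feature count, >= 1.
#' @return 2, 3 or 5.
#' @examples
#' choose_pace(2500)  # 5
#' choose_pace(1500)  # 3
#' choose_pace(800)   # 2
#' @export
choose_pace <- function(d1) {
  if (d1 < 1) stop("d1 must be >= 1")
  if (d1 > 2000) 5L else if (d1 > 1000) 3L else 2L
}

#' Stratified K-fold split
#'
#' Samples of each class are shuffled (seed-deterministically) and dealt
#' into K folds so that every fold receives a near-equal share of each
#' class and overall fold sizes differ by at most one. Extra samples from
#' the per-class remainders go to the currently smallest folds.
#'
#' @param n_samples total sample count.
#' @param labels binary labels of length `n_samples`.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return List of `k` integer index vectors: disjoint, covering
#'   `1:n_samples`.
#' @export
kfold_split <- function(n_samples, labels, k = 4L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (length(labels) != n_samples)
    stop("labels length differs from n_samples")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop("class '", small[1L], "' has ", counts[small[1L]],
         " samples, fewer than k = ", k)
  folds <- vector("list", k)
  sizes <- integer(k)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # folds currently smallest (ties -> lowest index) absorb the remainder
      per_fold <- rep(base, k)
      if (extra > 0L) {
        recv <- order(sizes, seq_len(k))[seq_len(extra)]
        per_fold[recv] <- per_fold[recv] + 1L
      }
      at <- 1L
      for (f in seq_len(k)) {
        if (per_fold[f] > 0L) {
          folds[[f]] <- c(folds[[f]], idx[at:(at + per_fold[f] - 1L)])
          at <- at + per_fold[f]
        }
        sizes[f] <- sizes[f] + per_fold[f]
      }
    }
  })
  lapply(folds, sort)
}

# z-score columns of train by its own statistics, apply the same location
# and scale to test (no leakage); near-constant columns get unit scale.
standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sd, "/"))
}

# Fit the classifier on every training fold of the current feature set.
# Returns per-fold models plus pooled out-of-fold probability predictions.
cv_fit <- function(values, labels, feature_ids, folds, hp) {
  X_all <- t(values[feature_ids, , drop = FALSE])
  oof <- numeric(ncol(values))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(X_all)), test_idx)
    z <- standardize_fold(X_all[train_idx, , drop = FALSE],
                          X_all[test_idx, , drop = FALSE])
    fit <- fit_logistic(z$train, labels[train_idx], hp)
    models[[f]] <- fit
    oof[test_idx] <- predict(fit, z$test)
  }
  list(models = models, oof_prob = oof)
}

cv_metrics <- function(labels, oof_prob) {
  pred <- as.integer(oof_prob >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(accuracy = (tp + tn) / length(labels),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

# Mean absolute standardized weight across folds, the RFE importance rule.
fold_importance <- function(models, feature_ids) {
  imp <- rowMeans(vapply(models, function(m) abs(m$weights[feature_ids]),
                         numeric(length(feature_ids))))
  stats::setNames(imp, feature_ids)
}

#' Recursive feature elimination with a logistic classifier
#'
#' Starting from all features of a (typically post-filter) labelled
#' matrix, each round fits the logistic classifier on every training fold
#' of a fixed stratified K-fold split, records the cross-validated
#' accuracy and F1 of the current feature set from pooled out-of-fold
#' predictions, ranks features by mean absolute standardised weight across
#' folds, and drops the `pace` least important (ties broken by gene id so
#' lexicographically smaller ids survive). Elimination stops once the
#' floor is reached; the final round never drops below it.
#'
#' @param mat labelled [expression_matrix()] (the post-filter matrix A1).
#' @param pace features eliminated per round; `NULL` (default) applies
#'   [choose_pace()] to the feature count.
#' @param k number of cross-validation folds (default 4).
#' @param floor smallest feature-set size to reach (default 1).
#' @param hp [logistic_hp()] training hyperparameters.
#' @param seed integer seed for the fold split.
#' @param select `"best"` returns the step maximising CV accuracy (ties:
#'   the smaller set); `"floor"` returns the final, floor-sized step —
#'   used when an exact target subset size is required.
#' @return An `RfePath`: list with `steps` (data frame: step, n_features,
#'   cv_accuracy, cv_f1), `feature_sets` (list of character vectors per
#'   step), `pace`, `k`, `best_step` and `selected_features`.
#' @export
rfe <- function(mat, pace = NULL, k = 4L, floor = 1L, hp = logistic_hp(),
                seed = 1L, select = c("best", "floor")) {
  select <- match.arg(select)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  check_two_classes(mat)
  features <- gene_ids(mat)
  if (anyDuplicated(features)) stop("gene ids must be unique")
  if (floor < 1L) stop("floor must be >= 1")
  if (length(features) < floor)
    stop("matrix has ", length(features), " features, fewer than floor = ",
         floor)
  if (is.null(pace)) pace <- choose_pace(length(features))
  folds <- kfold_split(ncol(mat$values), mat$labels, k = k, seed = seed)
  sets <- list()
  acc <- f1 <- numeric(0)
  current <- features
  repeat {
    fit <- cv_fit(mat$values, mat$labels, current, folds, hp)
    m <- cv_metrics(mat$labels, fit$oof_prob)
    sets[[length(sets) + 1L]] <- current
    acc <- c(acc, m$accuracy)
    f1 <- c(f1, m$f1)
    if (length(current) <= floor) break
    imp <- fold_importance(fit$models, current)
    n_drop <- min(pace, length(current) - floor)
    # ascending importance; among ties the lexicographically larger id is
    # dropped first, so smaller ids survive
    ord <- order(imp, current, decreasing = c(FALSE, TRUE),
                 method = "radix")
    drop_ids <- current[ord[seq_len(n_drop)]]
    current <- setdiff(current, drop_ids)
  }
  best <- if (select == "floor") {
    length(sets)
  } else {
    cand <- which(acc == max(acc))
    cand[length(cand)]  # sets shrink monotonically: last tie = smallest set
  }
  structure(list(steps = data.frame(step = seq_along(sets),
                                    n_features = lengths(sets),
                                    cv_accuracy = acc, cv_f1 = f1),
                 feature_sets = sets, pace = as.integer(pace),
                 k = as.integer(k), best_step = best,
                 selected_features = sets[[best]]),
            class = "RfePath")
}

#' @export
print.RfePath <- function(x, ...) {
  cat(sprintf(
    "RfePath: %d -> %d features in %d steps (pace %d, %d folds)\n",
    x$steps$n_features[1L], min(x$steps$n_features), nrow(x$steps),
    x$pace, x$k))
  cat(sprintf("  selected: %d features at step %d (CV accuracy %.3f)\n",
              length(x$selected_features), x$best_step,
              x$steps$cv_accuracy[x$best_step]))
  invisible(x)
}
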