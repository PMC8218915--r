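# From-scratch logistic regression trained by full-batch gradient descent
# on the mean cross-entropy cost. This is the classifier embedded in the
# recursive feature elimination loop; it is deliberately self-contained
# (no glm) because the feature-importance rule of the embedded layer is
# defined on its weight vector.

#' Numerically stable sigmoid
#'
#' `1 / (1 + exp(-j))`, with the argument clipped to +/-700 against
#' overflow and the result clamped to the largest doubles strictly inside
#' (0, 1), so no input ever yields exactly 0 or 1.
#'
#' @param j numeric vector.
#' @return Values strictly in (0, 1).
#' @examples
#' sigmoid(0)  # 0.5
#' @export
sigmoid <- function(j) {
  j <- pmin(pmax(j, -700), 700)
  p <- 1 / (1 + exp(-j))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Mean cross-entropy cost of predicted probabilities
#'
#' \deqn{J = \frac{1}{m}\sum_{i=1}^m \left[-y_i \ln a_i - (1-y_i)\ln(1-a_i)\right]}
#' with probabilities clipped to `[clip, 1 - clip]` before taking logs.
#'
#' @param a predicted probabilities in (0, 1).
#' @param y binary labels (0/1), same length as `a`.
#' @param clip probability clipping constant (default 1e-12).
#' @return Non-negative scalar.
#' @examples
#' logistic_cost(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
logistic_cost <- function(a, y, clip = 1e-12) {
  if (length(a) != length(y))
    stop("predictions and labels differ in length")
  a <- pmin(pmax(a, clip), 1 - clip)
  mean(-y * log(a) - (1 - y) * log(1 - a))
}

# Analytic gradient of the (optionally L2-penalised) mean cross-entropy
# with respect to (weights, bias). Shared by the trainer and the
# finite-difference checks.
logistic_gradient <- function(X, y, weights, bias, lambda = 0) {
  m <- nrow(X)
  a <- sigmoid(drop(X %*% weights) + bias)
  r <- a - y
  list(weights = drop(crossprod(X, r)) / m + lambda * weights / m,
       bias = mean(r))
}

#' Training hyperparameters for the logistic classifier
#'
#' @param learning_rate gradient-descent step size (default 0.1, suitable
#'   for z-scored features).
#' @param max_iter iteration cap (default 2000).
#' @param tol stop when the cost decreases by less than this between
#'   iterations (default 1e-7).
#' @param lambda L2 penalty weight; 0 (default) reproduces the plain
#'   unpenalised cost.
#' @param clip probability clipping constant for the cost (default 1e-12).
#' @return A list of class `logistic_hp`.
#' @export
logistic_hp <- function(learning_rate = 0.1, max_iter = 2000L, tol = 1e-7,
                        lambda = 0, clip = 1e-12) {
  stopifnot(learning_rate > 0, max_iter >= 1, tol >= 0, lambda >= 0)
  structure(list(learning_rate = learning_rate,
                 max_iter = as.integer(max_iter),
                 tol = tol, lambda = lambda, clip = clip),
            class = "logistic_hp")
}

#' Fit a logistic regression classifier by gradient descent
#'
#' Full-batch gradient descent on the mean cross-entropy cost, starting
#' from zero weights and bias, stopping at `max_iter` iterations or when
#' the cost improvement falls below `tol`. The per-iteration cost trace is
#' kept and checked to be non-increasing (to 1e-9); an increasing trace
#' aborts with an error naming the learning rate, since a too-large step
#' is the usual cause.
#'
#' Features are expected to be standardised (the embedded layer z-scores
#' per training fold before calling this).
#'
#' @param X samples x features numeric matrix, column names = feature ids.
#' @param y binary labels (0/1), one per row of `X`; both classes present.
#' @param hp a [logistic_hp()] object.
#' @return A `LogisticModel`: list with `weights` (named), `bias`,
#'   `training_trace` (cost per iteration) and `feature_ids`.
#' @export
fit_logistic <- function(X, y, hp = logistic_hp()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and labels differ in length")
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit the classifier")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  m <- nrow(X)
  p <- ncol(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(p))
  w <- rep(0, p)
  b <- 0
  trace <- numeric(hp$max_iter)
  prev <- Inf
  n_it <- 0L
  for (it in seq_len(hp$max_iter)) {
    z <- drop(X %*% w) + b
    a <- sigmoid(z)
    cost <- logistic_cost(a, y, clip = hp$clip) +
      hp$lambda / (2 * m) * sum(w^2)
    if (!is.finite(cost))
      stop("non-finite cost during training; reduce learning_rate (",
           hp$learning_rate, ")")
    if (cost > prev + 1e-9)
      stop("training cost increased at iteration ", it,
           "; reduce learning_rate (", hp$learning_rate, ")")
    trace[it] <- cost
    n_it <- it
    if (it > 1L && abs(prev - cost) < hp$tol) break
    r <- a - y
    gw <- drop(crossprod(X, r)) / m + hp$lambda * w / m
    gb <- mean(r)
    if (!all(is.finite(gw)) || !is.finite(gb))
      stop("non-finite gradient during training; reduce learning_rate (",
           hp$learning_rate, ")")
    w <- w - hp$learning_rate * gw
    b <- b - hp$learning_rate * gb
    prev <- cost
  }
  structure(list(weights = stats::setNames(w, ids), bias = b,
                 training_trace = trace[seq_len(n_it)],
                 feature_ids = ids),
            class = "LogisticModel")
}

#' @export
print.LogisticModel <- function(x, ...) {
  cat(sprintf("LogisticModel: %d features, %d iterations, final cost %.6g\n",
              length(x$weights), length(x$training_trace),
              x$training_trace[length(x$training_trace)]))
  invisible(x)
}

#' Predicted class probabilities from a fitted logistic model
#'
#' @param object a `LogisticModel`.
#' @param newdata samples x features matrix with the model's features (by
#'   column name when named, by position otherwise).
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls at 0.5.
#' @param ... unused.
#' @return Numeric vector of probabilities or integer 0/1 calls.
#' @export
predict.LogisticModel <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$feature_ids %in% colnames(X)))
    X <- X[, object$feature_ids, drop = FALSE]
  if (ncol(X) != length(object$weights))
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object$weights))
  p <- sigmoid(drop(X %*% object$weights) + object$bias)
  if (type == "class") as.integer(p >= 0.5) else p
}
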