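# Independent oracles: literal, term-by-term evaluations of the formulas
# under test, coded separately from the package's vectorised paths.

# Fisher score, one loop iteration per class, no shared code with the
# implementation.
oracle_fisher <- function(values, labels, denominator = "within_class") {
  mu <- sum(values) / length(values)
  classes <- unique(labels)
  num <- 0
  wcv <- 0
  for (k in classes) {
    v <- values[labels == k]
    nk <- length(v)
    muk <- sum(v) / nk
    sigk2 <- sum((v - muk)^2) / nk
    num <- num + nk * (muk - mu)^2
    wcv <- wcv + nk * sigk2
  }
  den <- if (denominator == "within_class") wcv
         else sum((values - mu)^2) / length(values)
  if (den < 1e-12) {
    if (num < 1e-12) return(0)
    return(min(num / 1e-12, 1e12))
  }
  num / den
}

# Mean cross-entropy, explicit per-sample loop.
oracle_cost <- function(a, y) {
  total <- 0
  for (i in seq_along(a))
    total <- total + (-y[i] * log(a[i]) - (1 - y[i]) * log(1 - a[i]))
  total / length(a)
}

# AUC as the Mann-Whitney concordant-pair fraction (ties counted 1/2),
# by exhaustive pair enumeration.
oracle_auc_pairs <- function(y_true, scores) {
  pos <- scores[y_true == 1]
  neg <- scores[y_true == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Average precision by exhaustive enumeration of descending unique-score
# thresholds.
oracle_average_precision <- function(y_true, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y_true == 1)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    called <- scores >= t
    tp <- sum(called & y_true == 1)
    recall <- tp / n_pos
    precision <- tp / sum(called)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Central finite differences of the logistic cost in every coordinate.
# The cost is evaluated in the numerically exact log1p form
# (equal to mean cross-entropy of the sigmoid, smooth everywhere).
oracle_numeric_gradient <- function(X, y, w, b, lambda = 0, eps = 1e-5) {
  m <- nrow(X)
  f <- function(w, b) {
    z <- drop(X %*% w) + b
    mean(pmax(z, 0) - y * z + log1p(exp(-abs(z)))) +
      lambda / (2 * m) * sum(w^2)
  }
  gw <- numeric(length(w))
  for (j in seq_along(w)) {
    e <- rep(0, length(w)); e[j] <- eps
    gw[j] <- (f(w + e, b) - f(w - e, b)) / (2 * eps)
  }
  gb <- (f(w, b + eps) - f(w, b - eps)) / (2 * eps)
  list(weights = gw, bias = gb)
}

# Greedy backward elimination, coded independently of rfe(): own fold
# loop, own standardisation and tie-break, the same importance rule
# (mean |standardised weight| across folds) and the same classifier
# primitive. Returns the features dropped, in elimination order.
oracle_greedy_elimination <- function(mat, folds, floor = 1L,
                                      hp = logistic_hp()) {
  current <- rownames(mat$values)
  dropped <- character(0)
  while (length(current) > floor) {
    imp_sum <- stats::setNames(rep(0, length(current)), current)
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(ncol(mat$values)), test_idx)
      Xtr <- t(mat$values[current, train_idx, drop = FALSE])
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2, stats::sd)
      sd[!is.finite(sd) | sd < 1e-12] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
      fit <- fit_logistic(Xtr, mat$labels[train_idx], hp)
      imp_sum <- imp_sum + abs(fit$weights[current])
    }
    imp <- imp_sum / length(folds)
    worst_val <- min(imp)
    ties <- names(imp)[imp == worst_val]
    victim <- sort(ties, decreasing = TRUE)[1L]  # larger id dropped first
    dropped <- c(dropped, victim)
    current <- setdiff(current, victim)
  }
  dropped
}

# Small random labelled matrix on the log2 scale.
random_labelled_matrix <- function(n_genes, n0, n1, seed) {
  cfg <- sim_config(n_genes = n_genes, n_samples_per_class = c(n0, n1),
                    n_informative = 0L, seed = seed)
  simulate_expression(cfg)$matrix
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
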