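test_that("confusion metrics reproduce enumerated counts", {
  # tp=2 tn=3 fp=1 fn=0, frozen by hand from the count definitions
  y_true <- c(1, 1, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 0)
  m <- confusion_metrics(y_true, y_pred)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(2L, 3L, 1L, 0L))
  expect_equal(m$acc, 5 / 6)
  expect_equal(m$pre, 2 / 3)
  expect_equal(m$f1, 0.8)

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$f1, 1)

  none <- confusion_metrics(c(1, 0, 1), c(0, 0, 0))
  expect_true(is.na(none$pre))
  expect_equal(none$f1, 0)

  expect_error(confusion_metrics(c(1, 0), 1), "length")
  expect_error(confusion_metrics(c(1, 2), c(0, 1)), "binary")
})

test_that("confusion metrics agree with independent counting on random pairs", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    m <- confusion_metrics(yt, yp)
    tab <- table(factor(yt, 0:1), factor(yp, 0:1))
    expect_identical(m$tp, unname(tab["1", "1"]))
    expect_identical(m$tn, unname(tab["0", "0"]))
    expect_identical(m$fp, unname(tab["0", "1"]))
    expect_identical(m$fn, unname(tab["1", "0"]))
    expect_equal(m$acc, mean(yt == yp))
  }
})

test_that("ROC handles separable, uninformative and tied scores", {
  r <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1)
  expect_equal(r$gini, 1)
  flat <- roc_curve(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)
  # frozen: 4 samples, one inversion -> 3 of 4 pairs concordant
  inv <- roc_curve(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(inv$auc, 0.75)
  expect_equal(inv$auc, oracle_auc_pairs(c(1, 1, 0, 0),
                                         c(0.9, 0.4, 0.6, 0.1)))
  # endpoints always present
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoidal AUC equals the concordant-pair fraction, gini = 2auc-1", {
  set.seed(29)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    yt <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    r <- roc_curve(yt, sc)
    expect_equal(r$auc, oracle_auc_pairs(yt, sc), tolerance = 1e-12)
    expect_identical(r$gini, 2 * r$auc - 1)
  }
})

test_that("ROC AUC cross-checks against an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    yt <- c(0, 1, rbinom(28, 1, 0.5))
    sc <- rnorm(30)
    want <- as.numeric(pROC::auc(pROC::roc(yt, sc, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_curve(yt, sc)$auc, want, tolerance = 1e-12)
  }
})

test_that("precision-recall curve matches enumeration and analytic cases", {
  p <- pr_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(p$auc_pr, 1)
  # single positive ranked last of n: average precision = 1/n
  n <- 7
  yt <- c(rep(0, n - 1), 1)
  sc <- seq(n, 1)
  expect_equal(pr_curve(yt, sc)$auc_pr, 1 / n)
  set.seed(37)
  for (i in 1:40) {
    m <- sample(4:40, 1)
    yt <- c(0, 1, rbinom(m - 2, 1, 0.4))
    sc <- round(runif(m), 2)
    expect_equal(pr_curve(yt, sc)$auc_pr,
                 oracle_average_precision(yt, sc), tolerance = 1e-12)
  }
})

test_that("Euclidean distances are exact, symmetric and zero-diagonal", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(NULL, c("x", "y")))
  d <- euclidean_distance_matrix(m)
  expect_equal(d["x", "y"], 5)
  expect_equal(diag(d), c(x = 0, y = 0))
  set.seed(41)
  vals <- matrix(rnorm(60), 10, 6)
  d2 <- euclidean_distance_matrix(vals)
  expect_equal(d2, t(d2))
  # spot-check against the explicit formula
  expect_equal(d2[2, 5], sqrt(sum((vals[, 2] - vals[, 5])^2)))
  # triangle inequality on sampled triples
  for (i in 1:20) {
    t3 <- sample(6, 3)
    expect_lte(d2[t3[1], t3[2]],
               d2[t3[1], t3[3]] + d2[t3[3], t3[2]] + 1e-12)
  }
})

test_that("cluster order keeps well-separated blobs contiguous", {
  set.seed(43)
  blob <- cbind(matrix(rnorm(40, 0), 4, 10), matrix(rnorm(40, 20), 4, 10))
  ord <- cluster_order(euclidean_distance_matrix(blob))
  expect_setequal(ord, 1:20)
  groups <- rep(1:2, each = 10)[ord]
  expect_identical(length(rle(groups)$lengths), 2L)
  expect_identical(cluster_order(matrix(0, 1, 1)), 1L)
  expect_error(cluster_order(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("evaluation report bundles consistent metrics and writes JSON", {
  set.seed(47)
  yt <- rep(c(0, 1), each = 10)
  sc <- plogis(rnorm(20, mean = ifelse(yt == 1, 1.5, -1.5)))
  rep <- evaluation_report(yt, sc)
  expect_identical(rep$tp + rep$tn + rep$fp + rep$fn, 20L)
  expect_identical(rep$gini, 2 * rep$auc - 1)
  cm <- confusion_metrics(yt, as.integer(sc >= 0.5))
  expect_equal(rep$acc, cm$acc)

  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path)
  got <- jsonlite::read_json(path)
  expect_equal(got$acc, rep$acc)
  expect_equal(got$auc, rep$auc)
  expect_identical(got$counts$tp, rep$tp)
})

test_that("heatmap export writes the cluster-ordered matrix", {
  sim <- simulate_expression(sim_config(
    n_genes = 30, n_samples_per_class = c(6, 6), n_informative = 10,
    effect_size = 4, seed = 51))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ord <- export_heatmap(sim$matrix, tsv)
  expect_setequal(ord, 1:12)
  back <- read_matrix(tsv)
  expect_identical(colnames(back$values),
                   colnames(sim$matrix$values)[ord])
})
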