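test_that("elimination pace follows the dimensional bands", {
  expect_identical(choose_pace(2500), 5L)
  expect_identical(choose_pace(1500), 3L)
  expect_identical(choose_pace(800), 2L)
  # open boundaries resolve to the finer pace
  expect_identical(choose_pace(2000), 3L)
  expect_identical(choose_pace(1000), 2L)
  expect_identical(choose_pace(2001), 5L)
  expect_identical(choose_pace(1), 2L)
  expect_error(choose_pace(0), ">= 1")
})

test_that("stratified folds partition the samples with balanced classes", {
  lab <- rep(c(0, 1), each = 4)
  folds <- kfold_split(8, lab, k = 4, seed = 1)
  expect_length(folds, 4)
  expect_true(all(lengths(folds) == 2L))
  for (f in folds) expect_setequal(lab[f], c(0, 1))
  expect_setequal(unlist(folds), 1:8)

  # unbalanced case: overall fold sizes differ by at most one
  lab2 <- c(rep(0, 11), rep(1, 6))
  folds2 <- kfold_split(17, lab2, k = 4, seed = 2)
  expect_setequal(unlist(folds2), 1:17)
  expect_lte(diff(range(lengths(folds2))), 1L)
  expect_error(kfold_split(17, lab2, k = 7), "class '1' has 6")
})

test_that("folds are reproducible per seed and vary across seeds", {
  lab <- rep(c(0, 1), each = 20)
  a <- kfold_split(40, lab, k = 4, seed = 9)
  b <- kfold_split(40, lab, k = 4, seed = 9)
  c <- kfold_split(40, lab, k = 4, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("pace-1 elimination matches the independent greedy oracle", {
  hp <- logistic_hp(max_iter = 400)
  for (seed in 1:4) {
    sim <- simulate_expression(sim_config(
      n_genes = 6, n_samples_per_class = c(12, 12), n_informative = 2,
      effect_size = 3, seed = seed))
    mat <- sim$matrix
    folds <- kfold_split(24, mat$labels, k = 4, seed = seed)
    want_dropped <- oracle_greedy_elimination(mat, folds, floor = 1, hp = hp)
    path <- rfe(mat, pace = 1, k = 4, floor = 1, hp = hp, seed = seed)
    got_dropped <- vapply(seq_len(length(path$feature_sets) - 1L),
                          function(i) setdiff(path$feature_sets[[i]],
                                              path$feature_sets[[i + 1L]]),
                          "")
    expect_identical(got_dropped, want_dropped)
  }
})

test_that("a feature set at or below the floor is a single no-op step", {
  mat <- simulate_expression(sim_config(
    n_genes = 4, n_samples_per_class = c(8, 8), n_informative = 2,
    effect_size = 3, seed = 1))$matrix
  path <- rfe(mat, pace = 2, k = 4, floor = 5 - 1, hp = logistic_hp(max_iter = 200))
  expect_identical(nrow(path$steps), 1L)
  expect_setequal(path$selected_features, rownames(mat$values))
})

test_that("subset sizes shrink by the pace with a floor-respecting last step", {
  mat <- simulate_expression(sim_config(
    n_genes = 13, n_samples_per_class = c(10, 10), n_informative = 3,
    effect_size = 3, seed = 5))$matrix
  path <- rfe(mat, pace = 3, k = 4, floor = 2,
              hp = logistic_hp(max_iter = 200), seed = 5)
  sizes <- path$steps$n_features
  expect_identical(sizes, c(13L, 10L, 7L, 4L, 2L))
  expect_true(all(vapply(seq_along(sizes),
                         function(i) length(path$feature_sets[[i]]),
                         1L) == sizes))
  # selected set is a subset of the initial features
  expect_true(all(path$selected_features %in% rownames(mat$values)))
  # best step maximises CV accuracy, ties resolved to the smallest set
  best <- path$best_step
  expect_equal(path$steps$cv_accuracy[best], max(path$steps$cv_accuracy))
  later <- which(path$steps$cv_accuracy == max(path$steps$cv_accuracy))
  expect_identical(best, later[length(later)])
})

test_that("planted informative genes survive elimination", {
  sim <- simulate_expression(sim_config(
    n_genes = 200, n_samples_per_class = c(20, 20), n_informative = 5,
    effect_size = 3, seed = 17))
  rk <- rank_genes(sim$matrix, min_keep = 30, max_keep = 30)
  a1 <- apply_filter(sim$matrix, rk)
  path <- rfe(a1, pace = 2, k = 4, floor = 5,
              hp = logistic_hp(max_iter = 500), seed = 17, select = "floor")
  expect_identical(length(path$selected_features), 5L)
  expect_setequal(path$selected_features, sim$informative)
})

test_that("run_frl honours the filter cut and exact target dimension", {
  sim <- simulate_expression(sim_config(
    n_genes = 500, n_samples_per_class = c(15, 15), n_informative = 10,
    effect_size = 2.5, seed = 2))
  cfg <- frl_config(target_dim = 20, min_keep = 25, max_keep = 60,
                    max_iter = 500)
  res <- run_frl(sim$matrix, cfg, seed = 2)
  expect_lt(res$ranking$d1, 500)
  expect_identical(length(res$selected_features), 20L)
  expect_s3_class(res$report, "EvaluationReport")
  expect_identical(res$report$tp + res$report$tn + res$report$fp +
                     res$report$fn, 30L)
  # too-small matrix for the target is rejected
  expect_error(run_frl(sim$matrix, frl_config(target_dim = 501)),
               "fewer than target_dim")
})

test_that("the pipeline is deterministic for a fixed seed", {
  sim <- simulate_expression(sim_config(
    n_genes = 300, n_samples_per_class = c(12, 12), n_informative = 8,
    effect_size = 2.5, seed = 4))
  cfg <- frl_config(target_dim = 10, min_keep = 20, max_keep = 40,
                    max_iter = 300)
  r1 <- run_frl(sim$matrix, cfg, seed = 11)
  r2 <- run_frl(sim$matrix, cfg, seed = 11)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_equal(r1$report$acc, r2$report$acc)
  expect_equal(r1$path$steps, r2$path$steps)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_frl_result(r1, d1)
  write_frl_result(r2, d2)
  for (f in c("selected_features.tsv", "rfe_path.tsv", "metrics.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
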