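test_that("error metrics match direct recomputation", {
  expect_equal(mse(c(0, 1), c(0, 1)), 0)
  expect_equal(mse(c(0, 1), c(1, 0)), 1)
  expect_equal(mae(c(0, 1), c(1, 0)), 1)
  set.seed(71)
  a <- matrix(rnorm(20), 5L)
  p <- matrix(rnorm(20), 5L)
  expect_equal(mse(a, p), mean((a - p)^2))
  expect_equal(mae(a, p), mean(abs(a - p)))
  expect_error(mse(1:3, 1:4), "shapes differ")
})

test_that("fold assignment is stratified, seeded and stable", {
  labels <- rep(1:2, c(12L, 9L))
  f1 <- harf:::make_folds(labels, 3L, seed = 5L)
  f2 <- harf:::make_folds(labels, 3L, seed = 5L)
  expect_identical(f1, f2)
  for (cls in 1:2) {
    expect_true(all(table(f1[labels == cls]) >= 3L))
  }
  expect_error(harf:::make_folds(rep(1:2, c(2L, 10L)), 3L, seed = 1L),
               "fewer than k")
})

test_that("pooled CV metrics equal the size-weighted combination of fold metrics", {
  d <- sep_cohort(seed = 72L, n_per_class = c(12L, 12L))
  rep <- kfold_cv(d, "rf", k = 3L, seed = 4L, ntree = 20L)
  sizes <- tabulate(rep$folds, 3L)
  expect_equal(rep$pooled$mse,
               sum(rep$per_fold$mse * sizes) / sum(sizes))
  expect_equal(rep$pooled$mae,
               sum(rep$per_fold$mae * sizes) / sum(sizes))
  # and against direct recomputation from the stored predictions
  expect_equal(rep$pooled$mse, mse(d$responses, rep$predictions))
})

test_that("cross validation is reproducible run to run", {
  d <- sep_cohort(seed = 73L, n_per_class = c(10L, 10L))
  r1 <- kfold_cv(d, "harf", seed = 6L, ntree = 15L)
  r2 <- kfold_cv(d, "harf", seed = 6L, ntree = 15L)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$categories, r2$categories)
  expect_identical(r1$folds, r2$folds)
})

test_that("HARF on a one-type cohort reproduces the plain forest report", {
  d <- toy_data(n = 18L, M = 4L, K = 1L, seed = 74L)
  rh <- kfold_cv(d, "harf", seed = 3L, ntree = 10L, aggregate = "leaf_mean")
  rf <- kfold_cv(d, "rf", seed = 3L, ntree = 10L, aggregate = "leaf_mean")
  expect_identical(rh$predictions, rf$predictions)
  expect_identical(rh$per_fold$mse, rf$per_fold$mse)
})

test_that("misclassification is reported for classifying models only", {
  d <- sep_cohort(seed = 75L, n_per_class = c(9L, 9L))
  rh <- kfold_cv(d, "harf", seed = 2L, ntree = 15L)
  rr <- kfold_cv(d, "rf", seed = 2L, ntree = 15L)
  expect_false(is.na(rh$pooled$misclassification_rate))
  expect_true(is.na(rr$pooled$misclassification_rate))
  expect_gte(rh$pooled$misclassification_rate, 0)
  expect_lte(rh$pooled$misclassification_rate, 1)
  # confusion-matrix oracle
  cm <- table(factor(rh$categories, 1:2), factor(d$labels, 1:2))
  expect_equal(rh$pooled$misclassification_rate,
               1 - sum(diag(cm)) / sum(cm))
})

test_that("keeping all trees makes the top-tree experiment an identity", {
  d <- sep_cohort(seed = 76L)
  out <- top_trees_experiment(d, top_frac = 1, ntree = 30L, seed = 5L)
  expect_equal(out$top_trees_mae, out$all_trees_mae)
  out2 <- top_trees_experiment(d, top_frac = 1, ntree = 30L, seed = 5L)
  expect_identical(out$all_trees_mae, out2$all_trees_mae)
})

test_that("one-hot indicators are well formed and vanish for one type", {
  d <- sep_cohort(seed = 77L, n_per_class = c(8L, 8L))
  oh <- one_hot_dataset(d)
  expect_equal(oh$M, d$M + 2L)
  ind <- oh$features[, d$M + 1:2]
  expect_true(all(rowSums(ind) == 1))
  expect_true(all(ind %in% c(0, 1)))

  d1 <- toy_data(n = 10L, M = 3L, K = 1L, seed = 78L)
  expect_identical(one_hot_dataset(d1)$features, d1$features)

  rep <- kfold_cv(d, "one_hot_rf", seed = 2L, ntree = 10L)
  expect_true(is.finite(rep$pooled$mse))
})

test_that("two-stage C agrees with HARF wherever the classifiers agree", {
  d <- sep_cohort(seed = 79L, n_per_class = c(15L, 15L))
  seedm <- 11L
  ts <- two_stage_fit(d, "C", ntree = 40L, mtry = 10L, n_size = 4L,
                      seed = seedm)
  hm <- harf_fit(d, ntree = 40L, mtry = 10L, n_size = 4L, seed = seedm)
  expect_identical(ts$forest$trees, hm$forest$trees)
  newx <- d$features
  pr_ts <- two_stage_predict(ts, newx)
  pr_h <- harf_predict(hm, newx)
  same <- which(pr_ts$category == pr_h$category)
  expect_gt(length(same), 0L)
  expect_equal(pr_ts$response[same, , drop = FALSE],
               pr_h$response[same, , drop = FALSE])
})

test_that("two-stage B on a one-type cohort assigns every tree to that type", {
  d <- toy_data(n = 16L, M = 4L, K = 1L, seed = 80L)
  ts <- two_stage_fit(d, "B", ntree = 8L, mtry = 4L, n_size = 4L, seed = 3L)
  expect_true(all(ts$tree_class == 1L))
  pr <- two_stage_predict(ts, d$features)
  expect_true(all(pr$category == 1L))
  expect_identical(pr$response,
                   forest_predict(ts$forest, d$features,
                                  aggregate = "leaf_mean"))
})

test_that("the threshold sweep at 0.5 reproduces the default HARF report", {
  d <- sep_cohort(seed = 81L, n_per_class = c(9L, 9L))
  sw <- threshold_sweep(d, thresholds = 0.5, seed = 4L, ntree = 20L)
  rep <- kfold_cv(d, "harf", seed = 4L, ntree = 20L)
  expect_equal(sw$curve$mse, rep$pooled$mse)
  expect_equal(sw$curve$mae, rep$pooled$mae)
  expect_equal(sw$curve$misclassification_rate,
               rep$pooled$misclassification_rate)
})

test_that("the threshold sweep is monotone in category-1 calls and non-negative", {
  d <- sep_cohort(seed = 82L, n_per_class = c(9L, 9L))
  sw <- threshold_sweep(d, thresholds = seq(0.45, 0.55, by = 0.05),
                        seed = 4L, ntree = 20L)
  expect_true(all(sw$curve$mse >= 0))
  n1 <- vapply(sw$reports, function(rp) sum(rp$categories == 1L), numeric(1L))
  expect_true(all(diff(n1) <= 0))
  expect_error(threshold_sweep(toy_data(K = 1L), seed = 1L), "two cancer")
})
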