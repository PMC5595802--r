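test_that("identity covariance reduces the multivariate cost to summed univariate costs", {
  set.seed(41)
  Y <- matrix(rnorm(12 * 3), 12L, 3L)
  want <- sum(vapply(1:3, function(c) node_cost(Y[, c]), numeric(1L)))
  expect_equal(mahalanobis_cost(Y, Lambda = diag(3L), ridge = 0), want)
})

test_that("degenerate nodes cost zero", {
  expect_equal(mahalanobis_cost(matrix(c(0.4, 0.7), 1L)), 0)
  Yc <- matrix(rep(c(1, 2, 3), each = 5L), 5L, 3L)
  expect_equal(mahalanobis_cost(Yc), 0, tolerance = 1e-8)
})

test_that("the cost matches the base-R Mahalanobis oracle", {
  set.seed(42)
  Y <- matrix(rnorm(10 * 3), 10L, 3L)
  mu <- colMeans(Y)
  Lam <- crossprod(sweep(Y, 2L, mu)) / nrow(Y)
  rg <- 1e-6 * sum(diag(Lam)) / 3
  want <- sum(stats::mahalanobis(Y, mu, Lam + diag(rg, 3L)))
  expect_equal(mahalanobis_cost(Y, ridge = rg), want, tolerance = 1e-10)
})

test_that("the self-normalized cost is invariant under affine recoding", {
  set.seed(43)
  Y <- matrix(rnorm(15 * 2), 15L, 2L)
  A <- matrix(c(2, 0.5, -1, 3), 2L, 2L)
  Yt <- Y %*% A + matrix(c(10, -4), 15L, 2L, byrow = TRUE)
  expect_equal(mahalanobis_cost(Y, ridge = 0),
               mahalanobis_cost(Yt, ridge = 0), tolerance = 1e-8)
})

test_that("gains under the parent-fixed covariance are non-negative for all bipartitions", {
  set.seed(44)
  Y <- matrix(rnorm(8 * 2), 8L, 2L)
  mu <- colMeans(Y)
  Lam <- crossprod(sweep(Y, 2L, mu)) / nrow(Y)
  parent <- mahalanobis_cost(Y, Lambda = Lam)
  for (left in all_bipartitions(8L)) {
    gain <- parent -
      mahalanobis_cost(Y[left, , drop = FALSE], Lambda = Lam) -
      mahalanobis_cost(Y[-left, , drop = FALSE], Lambda = Lam)
    expect_gte(gain, -1e-9)
  }
})

test_that("with one response the Mahalanobis tree topology matches the univariate fit", {
  d <- toy_data(n = 30L, M = 6L, r = 1L, seed = 45L)
  fu <- fit_forest(d, ntree = 5L, mtry = 3L, n_size = 4L, seed = 6L,
                   cost = "sse")
  fm <- fit_forest(d, ntree = 5L, mtry = 3L, n_size = 4L, seed = 6L,
                   cost = "mahalanobis")
  strip <- function(f) lapply(f$trees, function(tr) {
    lapply(tr, function(nd) nd[intersect(names(nd),
                                         c("leaf", "feature", "threshold",
                                           "left", "right", "members"))])
  })
  expect_identical(strip(fu), strip(fm))
})

test_that("correlated responses can reverse the chosen split", {
  # y1, y2 strongly correlated; feature 1 separates along the thin (1, -1)
  # direction, feature 2 along the wide (1, 1) direction with a larger raw
  # gap, so the summed univariate cost and the Mahalanobis cost disagree
  t <- c(0, 1, 2, 3, 0.1, 1.1, 2.1, 3.1)
  g1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  g2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  Y <- cbind(t + 0.15 * g1 + 0.6 * g2, t - 0.15 * g1 + 0.6 * g2)
  X <- cbind(g1, g2)
  expect_equal(best_split(X, Y, 1:2, cost = "mahalanobis")$feature, 1L)
  expect_equal(best_split(X, Y, 1:2, cost = "sse")$feature, 2L)
})

test_that("fit_mrf validates its inputs and is reproducible", {
  d1 <- toy_data(n = 12L, M = 3L, r = 1L, seed = 46L)
  expect_error(fit_mrf(d1), "r >= 2")
  d <- toy_data(n = 20L, M = 4L, r = 2L, seed = 47L)
  f1 <- fit_mrf(d, ntree = 6L, mtry = 3L, n_size = 4L, seed = 8L)
  f2 <- fit_mrf(d, ntree = 6L, mtry = 3L, n_size = 4L, seed = 8L)
  expect_identical(f1$trees, f2$trees)
  expect_equal(f1$cost, "mahalanobis")
})

test_that("single-class mHARF equals the multivariate forest prediction", {
  d <- toy_data(n = 20L, M = 4L, r = 2L, K = 1L, seed = 48L)
  mdl <- harf_fit(d, ntree = 8L, mtry = 3L, n_size = 4L, seed = 2L,
                  multivariate = TRUE)
  set.seed(4)
  newx <- matrix(rnorm(6L * d$M), 6L)
  pr <- mharf_predict(mdl, newx)
  expect_true(all(pr$category == 1L))
  expect_identical(pr$response,
                   forest_predict(mdl$forest, newx, aggregate = "leaf_mean"))
})

test_that("heterogeneity-aware selection helps joint multi-drug prediction", {
  # three drugs, only the first separating the two types
  prof <- cbind(c(rep(1, 5), rep(5 / 17, 5)), rep(1, 10), rep(0.6, 10))
  d <- make_dataset(sim_config(drug_inhibition = prof), seed = 301L)
  r_mrf <- kfold_cv(d, "mrf", seed = 1L)
  r_mh <- kfold_cv(d, "mharf", seed = 1L)
  expect_lt(r_mh$pooled$mse, r_mrf$pooled$mse)
  expect_equal(r_mh$pooled$misclassification_rate, 0, tolerance = 0.1)
})

test_that("the per-child covariance variant grows valid trees", {
  d <- toy_data(n = 16L, M = 3L, r = 2L, seed = 49L)
  f <- fit_mrf(d, ntree = 3L, mtry = 2L, n_size = 6L, seed = 1L,
               per_child = TRUE)
  for (tr in f$trees) {
    leaves <- Filter(function(nd) nd$leaf, tr)
    expect_equal(sum(vapply(leaves, function(l) l$n, numeric(1L))), d$n)
  }
})
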