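test_that("node cost is the centered sum of squares", {
  expect_equal(node_cost(c(0.3, 0.3, 0.3)), 0)
  expect_equal(node_cost(c(1, 3)), 2)
  set.seed(11)
  y <- rnorm(20)
  expect_equal(node_cost(y), (length(y) - 1) * var(y))
  expect_error(node_cost(numeric(0)), "empty")
})

test_that("split gain is the parent-minus-children cost reduction", {
  expect_equal(split_gain(c(1, 3), 1, 3), 2)
  expect_equal(split_gain(rep(2, 4), rep(2, 2), rep(2, 2)), 0)
  expect_error(split_gain(c(1, 2), numeric(0), c(1, 2)), "non-empty")
  expect_error(split_gain(c(1, 2, 3), c(1, 2), c(5)), "partition")
})

test_that("every bipartition of a node has non-negative gain", {
  set.seed(5)
  y <- rnorm(8)
  for (left in all_bipartitions(8L)) {
    expect_gte(split_gain(y, y[left], y[-left]), -1e-12)
  }
})

test_that("best_split finds the perfect separator and refuses constants", {
  X <- matrix(1:4, ncol = 1L)
  y <- c(0, 0, 1, 1)
  sp <- best_split(X, y, 1L)
  expect_equal(sp$feature, 1L)
  expect_gt(sp$threshold, 2)
  expect_lt(sp$threshold, 3)
  expect_equal(sp$gain, node_cost(y))

  Xc <- matrix(1, 5L, 3L)
  expect_null(best_split(Xc, rnorm(5), 1:3))
})

test_that("best_split agrees with the exhaustive oracle on random nodes", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    X <- matrix(rnorm(8 * 3), 8L, 3L)
    y <- rnorm(8)
    got <- best_split(X, y, 1:3)
    want <- brute_best_split(X, y, 1:3)
    expect_equal(got$feature, want$feature)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$gain, want$gain, tolerance = 1e-9)
  }
})

test_that("grow_tree respects n_size and records leaf bookkeeping", {
  d <- toy_data(n = 10L, M = 3L, seed = 2L)
  set.seed(1)
  tr <- grow_tree(d$features, d$responses, d$labels, d$K, mtry = 3L,
                  n_size = 99L)
  expect_length(tr, 1L)
  leaf <- tr[[1L]]
  expect_true(leaf$leaf)
  expect_equal(leaf$members, 1:10)
  expect_equal(leaf$mean, mean(d$responses), ignore_attr = TRUE)
  expect_equal(sum(leaf$class_counts), 10L)

  # perfectly separable toy, fully grown: all leaves have zero cost
  X <- matrix(c(1, 2, 3, 4), ncol = 1L)
  y <- c(0, 0, 1, 1)
  set.seed(1)
  tr2 <- grow_tree(X, y, labels = rep(1L, 4L), K = 1L, mtry = 1L, n_size = 1L)
  leaves <- Filter(function(nd) nd$leaf, tr2)
  expect_gt(length(tr2), 1L)
  for (l in leaves) expect_equal(node_cost(y[l$members]), 0)
})

test_that("tree growth is deterministic under a fixed seed", {
  d <- toy_data(n = 30L, M = 6L, seed = 3L)
  set.seed(42)
  b1 <- sample.int(30L, 30L, replace = TRUE)
  t1 <- grow_tree(d$features, d$responses, d$labels, d$K, 4L, 4L, boot = b1)
  set.seed(42)
  b2 <- sample.int(30L, 30L, replace = TRUE)
  t2 <- grow_tree(d$features, d$responses, d$labels, d$K, 4L, 4L, boot = b2)
  expect_identical(t1, t2)
})

test_that("fit_forest is reproducible and every leaf satisfies its invariants", {
  d <- sep_cohort(seed = 4L, n_per_class = c(30L, 30L))
  f1 <- fit_forest(d, ntree = 100L, mtry = 10L, n_size = 4L, seed = 9L)
  f2 <- fit_forest(d, ntree = 100L, mtry = 10L, n_size = 4L, seed = 9L)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$boot, f2$boot)

  for (t in seq_len(f1$ntree)) {
    tr <- f1$trees[[t]]
    leaves <- Filter(function(nd) nd$leaf, tr)
    # multiplicity counts across leaves partition the bootstrap sample
    expect_equal(sum(vapply(leaves, function(l) l$n, numeric(1L))), d$n)
    counts <- Reduce(`+`, lapply(leaves, function(l) l$class_counts))
    expect_equal(counts, tabulate(d$labels[f1$boot[[t]]], d$K))
    for (l in leaves) {
      expect_gt(length(l$members), 0L)
      expect_equal(sum(l$class_counts), l$n)
    }
  }
  expect_error(fit_forest(d, mtry = 200L), "mtry")
  expect_error(fit_forest(d, ntree = 0L), "ntree")
})

test_that("per-tree weights are an average over the reached leaf", {
  tree <- as_harf_tree(leaf_node(members = c(2L, 5L), mean = 1,
                                 class_counts = c(2L, 0L)))
  w <- tree_weights(tree, c(0, 0), n_train = 6L)
  expect_equal(w, c(0, 0.5, 0, 0, 0.5, 0))

  d <- toy_data(n = 24L, M = 4L, seed = 6L)
  f <- fit_forest(d, ntree = 10L, mtry = 4L, n_size = 4L, seed = 2L)
  for (rep in 1:10) {
    set.seed(rep)
    x <- rnorm(d$M)
    for (tr in f$trees) {
      w <- tree_weights(tr, x, d$n)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
})

test_that("forest prediction reproduces the two-cluster vote arithmetic", {
  m <- seventy_thirty_model()
  x <- c(0, 0)
  expect_equal(forest_predict(m$forest, x, aggregate = "weights")[1L, 1L],
               0.325)
  expect_equal(forest_predict(m$forest, x, aggregate = "leaf_mean")[1L, 1L],
               0.325)
})

test_that("a single tree predicts its leaf mean", {
  d <- toy_data(n = 16L, M = 3L, seed = 8L)
  f <- fit_forest(d, ntree = 1L, mtry = 3L, n_size = 4L, seed = 5L,
                  bootstrap = FALSE)
  x <- d$features[3L, ]
  tr <- f$trees[[1L]]
  leaf <- tr[[harf:::route_sample(tr, x)]]
  expect_equal(forest_predict(f, x, aggregate = "leaf_mean")[1L, 1L],
               leaf$mean[1L])
})

test_that("weight form and leaf-mean form agree without bootstrap duplicates", {
  d <- toy_data(n = 24L, M = 5L, seed = 9L)
  f <- fit_forest(d, ntree = 15L, mtry = 3L, n_size = 4L, seed = 7L,
                  bootstrap = FALSE)
  set.seed(1)
  newx <- matrix(rnorm(20L * d$M), 20L)
  expect_equal(forest_predict(f, newx, aggregate = "weights"),
               forest_predict(f, newx, aggregate = "leaf_mean"),
               tolerance = 1e-12)
})

test_that("deterministic CART reduction: m = M, no bootstrap, one tree", {
  d <- toy_data(n = 18L, M = 4L, seed = 10L)
  f1 <- fit_forest(d, ntree = 1L, mtry = 4L, n_size = 4L, seed = 1L,
                   bootstrap = FALSE)
  f2 <- fit_forest(d, ntree = 1L, mtry = 4L, n_size = 4L, seed = 999L,
                   bootstrap = FALSE)
  newx <- d$features + 0.01
  expect_equal(forest_predict(f1, newx), forest_predict(f2, newx))
})

test_that("forest JSON serialization round-trips predictions exactly", {
  d <- toy_data(n = 20L, M = 4L, K = 2L, seed = 12L)
  f <- fit_forest(d, ntree = 8L, mtry = 3L, n_size = 4L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  save_forest(f, path)
  f2 <- load_forest(path)
  set.seed(2)
  newx <- matrix(rnorm(5L * d$M), 5L)
  expect_identical(forest_predict(f, newx), forest_predict(f2, newx))
  expect_equal(f2$ntree, f$ntree)
  expect_equal(f2$train_labels, f$train_labels)
})
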