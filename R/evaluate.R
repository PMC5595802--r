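#' Mean squared / absolute error
#'
#' Error between actual and predicted responses, averaged over every
#' (sample, drug) entry when the inputs are matrices.
#'
#' @param actual,predicted numeric vectors or matrices of equal shape.
#' @return Non-negative scalar.
#' @export
mse <- function(actual, predicted) {
  check_same_shape(actual, predicted)
  mean((as.matrix(actual) - as.matrix(predicted))^2)
}

#' @rdname mse
#' @export
mae <- function(actual, predicted) {
  check_same_shape(actual, predicted)
  mean(abs(as.matrix(actual) - as.matrix(predicted)))
}

check_same_shape <- function(a, p) {
  a <- as.matrix(a)
  p <- as.matrix(p)
  if (length(a) == 0L) stop("empty inputs")
  if (!all(dim(a) == dim(p))) stop("actual and predicted shapes differ")
  invisible(NULL)
}

#' Subset a dataset by sample rows
#'
#' Returns a new [harf_data] containing the selected samples; label
#' categories that lose all samples are dropped (with a warning) so `K`
#' stays consistent.
#'
#' @param data a [harf_data].
#' @param rows integer or logical row index.
#' @export
subset_samples <- function(data, rows) {
  stopifnot(inherits(data, "harf_data"))
  suppressWarnings(
    harf_data(data$features[rows, , drop = FALSE],
              data$responses[rows, , drop = FALSE],
              data$label_levels[data$labels[rows]],
              sample_ids = data$sample_ids[rows],
              feature_ids = data$feature_ids)
  )
}

#' Append one-hot cancer-type indicator features
#'
#' Adds K binary indicator columns (one per cancer type) to the feature
#' matrix, the standard way of handing type information to an otherwise
#' type-blind forest. Indicator columns that are constant across all samples
#' (as the single column of a K = 1 dataset is) are dropped, since a
#' constant feature can never be selected by a split and would only perturb
#' the feature numbering.
#'
#' @param data a [harf_data].
#' @return A [harf_data] with the augmented feature matrix.
#' @export
one_hot_dataset <- function(data) {
  stopifnot(inherits(data, "harf_data"))
  ind <- vapply(seq_len(data$K), function(cls) as.numeric(data$labels == cls),
                numeric(data$n))
  ind <- matrix(ind, nrow = data$n)
  colnames(ind) <- paste0("onehot_", data$label_levels)
  keep <- apply(ind, 2L, function(v) length(unique(v)) > 1L)
  if (!any(keep)) return(data)
  harf_data(cbind(data$features, ind[, keep, drop = FALSE]),
            data$responses, data$label_levels[data$labels],
            sample_ids = data$sample_ids)
}

# Stratified (or plain) fold assignment: within each class, shuffled sample
# positions are dealt round-robin into the k folds.
make_folds <- function(labels, k, seed, stratify = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cls in sort(unique(labels))) {
        rows <- which(labels == cls)
        if (length(rows) < k) {
          stop("class ", cls, " has ", length(rows),
               " samples, fewer than k = ", k,
               "; use stratify = FALSE or reduce k")
        }
        fold[sample(rows)] <- rep_len(seq_len(k), length(rows))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

# Fit on train, predict test, for one model specification. Returns
# list(response = matrix, category = integer or NA).
fit_predict_spec <- function(train, test, model, ntree, mtry, n_size, seed,
                             vote_threshold = 0.5, classifier_hook = NULL,
                             val_frac = 0.25, aggregate = "default") {
  m_eff <- function(d) min(mtry, d$M)
  # each method's canonical aggregation: pooled nearest-neighbour weights
  # for plain forests (the printed prediction formula), leaf means for the
  # heterogeneity-aware variants (the worked-example arithmetic)
  agg_f <- if (aggregate == "default") "weights" else aggregate
  agg_h <- if (aggregate == "default") "leaf_mean" else aggregate
  switch(model,
    rf = {
      f <- fit_forest(train, ntree, m_eff(train), n_size, seed)
      list(response = forest_predict(f, test$features, aggregate = agg_f),
           category = rep(NA_integer_, test$n))
    },
    cancer_specific_rf = {
      # one forest per cancer type; a test sample is predicted by the model
      # of its own (known) type
      resp <- matrix(NA_real_, test$n, train$r)
      seeds <- spawn_seeds(seed, train$K)
      for (cls in seq_len(train$K)) {
        lvl <- train$label_levels[cls]
        sub <- subset_samples(train, train$labels == cls)
        f <- fit_forest(sub, ntree, m_eff(sub), n_size, seeds[cls])
        rows <- which(test$label_levels[test$labels] == lvl)
        if (length(rows))
          resp[rows, ] <- forest_predict(f, test$features[rows, , drop = FALSE],
                                         aggregate = agg_f)
      }
      list(response = resp, category = rep(NA_integer_, test$n))
    },
    harf = {
      mdl <- harf_fit(train, ntree, m_eff(train), n_size, seed,
                      vote_threshold = vote_threshold)
      pr <- harf_predict(mdl, test$features, aggregate = agg_h)
      list(response = pr$response, category = pr$category)
    },
    mrf = {
      f <- fit_mrf(train, ntree, m_eff(train), n_size, seed)
      list(response = forest_predict(f, test$features, aggregate = agg_f),
           category = rep(NA_integer_, test$n))
    },
    mharf = {
      mdl <- harf_fit(train, ntree, m_eff(train), n_size, seed,
                      vote_threshold = vote_threshold, multivariate = TRUE)
      pr <- harf_predict(mdl, test$features, aggregate = agg_h)
      list(response = pr$response, category = pr$category)
    },
    one_hot_rf = {
      tr <- one_hot_dataset(train)
      f <- fit_forest(tr, ntree, m_eff(tr), n_size, seed)
      te <- one_hot_dataset(test)
      list(response = forest_predict(f, te$features, aggregate = agg_f),
           category = rep(NA_integer_, test$n))
    },
    two_stage_b = ,
    two_stage_c = {
      variant <- if (model == "two_stage_b") "B" else "C"
      mdl <- two_stage_fit(train, variant, classifier_hook,
                           val_frac = val_frac, ntree = ntree,
                           mtry = m_eff(train), n_size = n_size, seed = seed)
      pr <- two_stage_predict(mdl, test$features)
      list(response = pr$response, category = pr$category)
    },
    stop("unknown model spec: ", model)
  )
}

#' Stratified k-fold cross validation
#'
#' Deterministic (seeded) k-fold evaluation of any of the model
#' specifications: `"rf"` (integrated random forest), `"cancer_specific_rf"`
#' (one forest per cancer type, test samples predicted by their own type's
#' model, errors pooled), `"harf"`, `"mrf"`, `"mharf"`, `"one_hot_rf"`, and
#' the two-stage baselines `"two_stage_b"` / `"two_stage_c"`. Folds are
#' stratified by cancer type by default so that every training fold sees
#' every type; pooled metrics are computed over the union of held-out
#' predictions, not by averaging fold metrics.
#'
#' @param data a [harf_data].
#' @param model one of the specification strings above.
#' @param k number of folds (default 3).
#' @param seed integer seed controlling fold assignment and model fits.
#' @param stratify stratify folds by cancer type (default `TRUE`).
#' @param ntree,mtry,n_size forest parameters (defaults 100, 10, 4; `mtry`
#'   is capped at the number of available features).
#' @param vote_threshold HARF vote threshold (two-class case).
#' @param classifier_hook classifier factory for the two-stage variants; see
#'   [two_stage_fit].
#' @param val_frac validation fraction for two-stage tree categorization.
#' @param aggregate `"default"` uses each method's canonical aggregation
#'   (pooled weights for plain forests, leaf means for HARF variants);
#'   `"leaf_mean"` or `"weights"` forces one rule on every method (useful
#'   for exact reduction checks).
#' @return An object of class `harf_eval` with elements `per_fold` (data
#'   frame of fold metrics), `pooled` (list with `mse`, `mae`,
#'   `misclassification_rate`), `predictions`, `categories`, `folds`, plus
#'   the echoed configuration.
#' @export
kfold_cv <- function(data, model = "harf", k = 3L, seed = 1L,
                     stratify = TRUE, ntree = 100L, mtry = 10L, n_size = 4L,
                     vote_threshold = 0.5, classifier_hook = NULL,
                     val_frac = 0.25, aggregate = "default") {
  stopifnot(inherits(data, "harf_data"))
  folds <- make_folds(data$labels, k, seed, stratify)
  fold_seeds <- spawn_seeds(seed, k + 1L)[-1L]
  pred <- matrix(NA_real_, data$n, data$r)
  cats <- rep(NA_integer_, data$n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_rows <- which(folds == f)
    train <- subset_samples(data, folds != f)
    test <- subset_samples(data, test_rows)
    out <- fit_predict_spec(train, test, model, ntree, mtry, n_size,
                            fold_seeds[f], vote_threshold, classifier_hook,
                            val_frac, aggregate)
    pred[test_rows, ] <- out$response
    # map category back through the (possibly reduced) training level set
    cats[test_rows] <- if (all(is.na(out$category))) NA_integer_ else
      match(train$label_levels[out$category], data$label_levels)
    mis <- if (all(is.na(out$category))) NA_real_ else
      mean(cats[test_rows] != data$labels[test_rows])
    per_fold[[f]] <- data.frame(
      fold = f,
      mse = mse(data$responses[test_rows, , drop = FALSE], out$response),
      mae = mae(data$responses[test_rows, , drop = FALSE], out$response),
      misclassification_rate = mis
    )
  }
  structure(list(
    model = model, k = k, seed = seed, stratify = stratify,
    ntree = ntree, mtry = mtry, n_size = n_size,
    vote_threshold = vote_threshold,
    per_fold = do.call(rbind, per_fold),
    pooled = list(
      mse = mse(data$responses, pred),
      mae = mae(data$responses, pred),
      misclassification_rate = if (all(is.na(cats))) NA_real_ else
        mean(cats != data$labels)
    ),
    predictions = pred, categories = cats, folds = folds
  ), class = "harf_eval")
}

#' @export
print.harf_eval <- function(x, ...) {
  cat("<harf_eval> model = ", x$model, ", k = ", x$k, ", seed = ", x$seed,
      "\n", sep = "")
  cat(sprintf("  pooled MSE %.4f  MAE %.4f", x$pooled$mse, x$pooled$mae))
  if (!is.na(x$pooled$misclassification_rate))
    cat(sprintf("  misclassification %.3f", x$pooled$misclassification_rate))
  cat("\n")
  invisible(x)
}

# Stratified integer split of samples into parts proportional to `split`.
split_samples <- function(labels, split, seed) {
  part <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      rows <- sample(which(labels == cls))
      sizes <- floor(split * length(rows))
      while (sum(sizes) < length(rows)) {
        sizes[which.max(split * length(rows) - sizes)] <-
          sizes[which.max(split * length(rows) - sizes)] + 1L
      }
      part[rows] <- rep.int(seq_along(split), sizes)
    }
  })
  part
}

# Per-tree leaf-mean predictions: ntree x n matrix (first response column).
tree_level_predictions <- function(forest, X) {
  out <- matrix(NA_real_, forest$ntree, nrow(X))
  for (t in seq_len(forest$ntree)) {
    tr <- forest$trees[[t]]
    for (i in seq_len(nrow(X))) {
      out[t, i] <- tr[[route_sample(tr, X[i, ])]]$mean[1L]
    }
  }
  out
}

#' Top-trees selection experiment
#'
#' Tests whether all trees are equally useful for every cancer type. The
#' samples are split (stratified) into train / validation / test parts; a
#' forest is fitted on the training part; for each cancer type the trees are
#' ranked by their validation MAE on that type's samples and the best
#' `top_frac` kept; test samples of each type are then predicted with their
#' type's kept trees. Reported against predicting every test sample with all
#' trees. Univariate responses only.
#'
#' @param data a [harf_data].
#' @param split three fractions for train / validation / test (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param top_frac fraction of trees kept per type (default 0.5; 1.0 makes
#'   the experiment an identity check).
#' @param ntree,mtry,n_size forest parameters.
#' @param seed integer seed.
#' @return List with `all_trees_mae`, `top_trees_mae`, `per_class` (data
#'   frame), `kept` (list of kept tree indices per class) and the split
#'   assignment.
#' @export
top_trees_experiment <- function(data, split = c(0.6, 0.2, 0.2),
                                 top_frac = 0.5, ntree = 100L, mtry = 10L,
                                 n_size = 4L, seed = 1L) {
  stopifnot(inherits(data, "harf_data"), length(split) == 3L,
            abs(sum(split) - 1) < 1e-8, top_frac > 0, top_frac <= 1)
  part <- split_samples(data$labels, split, seed)
  if (any(tabulate(part, 3L) == 0L)) stop("degenerate split sizes")
  train <- subset_samples(data, part == 1L)
  f <- fit_forest(train, ntree, min(mtry, data$M), n_size,
                  spawn_seeds(seed, 1L))
  val_rows <- which(part == 2L)
  test_rows <- which(part == 3L)
  pv <- tree_level_predictions(f, data$features[val_rows, , drop = FALSE])
  pt <- tree_level_predictions(f, data$features[test_rows, , drop = FALSE])
  yv <- data$responses[val_rows, 1L]
  yt <- data$responses[test_rows, 1L]
  n_keep <- max(1L, floor(top_frac * ntree))
  kept <- list()
  top_pred <- numeric(length(test_rows))
  for (cls in seq_len(data$K)) {
    vc <- which(data$labels[val_rows] == cls)
    tree_mae <- rowMeans(abs(pv[, vc, drop = FALSE] -
                               matrix(yv[vc], ntree, length(vc), byrow = TRUE)))
    keep <- order(tree_mae)[seq_len(n_keep)] # stable: ties by tree index
    kept[[data$label_levels[cls]]] <- keep
    tc <- which(data$labels[test_rows] == cls)
    if (length(tc))
      top_pred[tc] <- colMeans(pt[keep, tc, drop = FALSE])
  }
  all_pred <- colMeans(pt)
  per_class <- do.call(rbind, lapply(seq_len(data$K), function(cls) {
    tc <- which(data$labels[test_rows] == cls)
    data.frame(class = data$label_levels[cls],
               all_trees_mae = mae(yt[tc], all_pred[tc]),
               top_trees_mae = mae(yt[tc], top_pred[tc]))
  }))
  list(all_trees_mae = mae(yt, all_pred),
       top_trees_mae = mae(yt, top_pred),
       per_class = per_class, kept = kept, part = part)
}

#' Default classifier hook: LDA on the most class-separating genes
#'
#' Factory for the explicit cancer-type classifier used by the two-stage
#' baselines. Features are ranked by their one-way F statistic between
#' cancer types on the training data and linear discriminant analysis is fit
#' on the top `n_features` (expression panels are wider than the sample
#' count, so LDA needs this reduction). The returned function maps a
#' training set to a prediction closure.
#'
#' @param n_features genes to keep (default 10).
#' @return `function(X, labels)` returning `function(newx) -> integer`.
#' @export
lda_classifier_hook <- function(n_features = 10L) {
  function(X, labels) {
    n <- nrow(X)
    K <- length(unique(labels))
    if (K == 1L) {
      only <- labels[1L]
      return(function(newx) {
        if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
        rep(as.integer(only), nrow(newx))
      })
    }
    grand <- colMeans(X)
    ssb <- numeric(ncol(X))
    ssw <- numeric(ncol(X))
    for (cls in sort(unique(labels))) {
      rows <- which(labels == cls)
      mu <- colMeans(X[rows, , drop = FALSE])
      ssb <- ssb + length(rows) * (mu - grand)^2
      ssw <- ssw + colSums(sweep(X[rows, , drop = FALSE], 2L, mu)^2)
    }
    fstat <- (ssb / pmax(K - 1L, 1L)) / pmax(ssw / pmax(n - K, 1L), 1e-12)
    sel <- order(fstat, decreasing = TRUE)[seq_len(min(n_features, ncol(X)))]
    fit <- MASS::lda(X[, sel, drop = FALSE], grouping = factor(labels))
    function(newx) {
      if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
      as.integer(as.character(
        stats::predict(fit, newx[, sel, drop = FALSE])$class))
    }
  }
}

#' Two-stage classify-then-regress baselines
#'
#' The natural competitors of HARF's simultaneous scheme. Both variants
#' classify a test sample's cancer type with an explicit classifier (LDA by
#' default, pluggable through `classifier_hook`), then:
#'
#' * **Variant B** pre-categorizes the trees: the forest is grown on a
#'   training subset, each tree is assigned the cancer type on which its
#'   validation MAE is lowest, and a test sample is predicted by the trees
#'   assigned to its classified type.
#' * **Variant C** keeps HARF's prediction stage: the response is the mean
#'   of the leaf means of the trees whose leaf majority (for that sample)
#'   matches the classified type.
#'
#' If no tree supports the classified type, all trees are used.
#'
#' @param data training [harf_data].
#' @param variant `"B"` or `"C"`.
#' @param classifier_hook factory `function(X, labels) -> function(newx)`;
#'   default [lda_classifier_hook()].
#' @param val_frac fraction of training samples held out (stratified) for
#'   tree categorization, variant B only (default 0.25).
#' @param ntree,mtry,n_size,seed forest parameters.
#' @return An object of class `two_stage_model`.
#' @export
two_stage_fit <- function(data, variant = c("B", "C"), classifier_hook = NULL,
                          val_frac = 0.25, ntree = 100L, mtry = 10L,
                          n_size = 4L, seed = 1L) {
  stopifnot(inherits(data, "harf_data"))
  variant <- match.arg(variant)
  hook <- classifier_hook %||% lda_classifier_hook()
  classify <- hook(data$features, data$labels)
  if (variant == "C") {
    forest <- fit_forest(data, ntree, min(mtry, data$M), n_size, seed)
    tree_class <- NULL
  } else {
    part <- split_samples(data$labels, c(1 - val_frac, val_frac), seed)
    train <- subset_samples(data, part == 1L)
    forest <- fit_forest(train, ntree, min(mtry, data$M), n_size,
                         spawn_seeds(seed, 1L))
    val_rows <- which(part == 2L)
    pv <- tree_level_predictions(forest,
                                 data$features[val_rows, , drop = FALSE])
    yv <- data$responses[val_rows, 1L]
    tree_class <- integer(ntree)
    per_class_mae <- matrix(NA_real_, ntree, data$K)
    for (cls in seq_len(data$K)) {
      vc <- which(data$labels[val_rows] == cls)
      per_class_mae[, cls] <-
        rowMeans(abs(pv[, vc, drop = FALSE] -
                       matrix(yv[vc], ntree, length(vc), byrow = TRUE)))
    }
    tree_class <- apply(per_class_mae, 1L, which.min)
  }
  structure(list(variant = variant, forest = forest, classify = classify,
                 tree_class = tree_class, K = data$K,
                 label_levels = data$label_levels),
            class = "two_stage_model")
}

#' @rdname two_stage_fit
#' @param model a fitted `two_stage_model`.
#' @param newx matrix of test samples (rows).
#' @return For `two_stage_predict`: list with `category` and `response`.
#' @export
two_stage_predict <- function(model, newx) {
  stopifnot(inherits(model, "two_stage_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  forest <- model$forest
  n_new <- nrow(newx)
  category <- model$classify(newx)
  response <- matrix(NA_real_, n_new, forest$r,
                     dimnames = list(rownames(newx),
                                     colnames(forest$y_train)))
  for (i in seq_len(n_new)) {
    x <- newx[i, ]
    sel <- if (model$variant == "B") {
      which(model$tree_class == category[i])
    } else {
      which(tree_votes(forest, x) == category[i])
    }
    if (length(sel) == 0L) sel <- seq_len(forest$ntree)
    acc <- numeric(forest$r)
    for (t in sel) {
      tr <- forest$trees[[t]]
      acc <- acc + tr[[route_sample(tr, x)]]$mean
    }
    response[i, ] <- acc / length(sel)
  }
  list(category = category, response = response)
}

#' Vote-threshold robustness sweep
#'
#' Re-evaluates a two-class HARF under a grid of vote thresholds, reusing
#' the same folds and the same fitted forests for every threshold (only the
#' classification decision changes), so the curve isolates the effect of the
#' threshold.
#'
#' @param data a two-class [harf_data].
#' @param thresholds numeric grid in (0, 1) (default 0.45 to 0.55).
#' @param k,seed,ntree,mtry,n_size as in [kfold_cv].
#' @return List with `curve` (data frame of threshold, pooled mse, mae,
#'   misclassification_rate) and `reports` (one `harf_eval`-like record per
#'   threshold).
#' @export
threshold_sweep <- function(data, thresholds = seq(0.45, 0.55, by = 0.01),
                            k = 3L, seed = 1L, ntree = 100L, mtry = 10L,
                            n_size = 4L) {
  stopifnot(inherits(data, "harf_data"))
  if (data$K != 2L) stop("threshold_sweep requires exactly two cancer types")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  folds <- make_folds(data$labels, k, seed, stratify = TRUE)
  fold_seeds <- spawn_seeds(seed, k + 1L)[-1L]
  n <- data$n
  votes1 <- integer(n)
  resp_by_cat <- array(NA_real_, c(n, data$r, 2L))
  resp_all <- matrix(NA_real_, n, data$r)
  for (f in seq_len(k)) {
    train <- subset_samples(data, folds != f)
    mdl <- harf_fit(train, ntree, min(mtry, data$M), n_size, fold_seeds[f])
    for (i in which(folds == f)) {
      x <- data$features[i, ]
      v <- tree_votes(mdl$forest, x)
      votes1[i] <- sum(v == 1L)
      means <- vapply(seq_along(v), function(t) {
        tr <- mdl$forest$trees[[t]]
        tr[[route_sample(tr, x)]]$mean
      }, numeric(data$r))
      means <- matrix(means, nrow = data$r)
      resp_all[i, ] <- rowMeans(means)
      for (cls in 1:2) {
        sel <- which(v == cls)
        resp_by_cat[i, , cls] <- if (length(sel))
          rowMeans(means[, sel, drop = FALSE]) else resp_all[i, ]
      }
    }
  }
  reports <- lapply(thresholds, function(th) {
    cat_i <- ifelse(votes1 >= th * ntree, 1L, 2L)
    pred <- matrix(NA_real_, n, data$r)
    for (i in seq_len(n)) pred[i, ] <- resp_by_cat[i, , cat_i[i]]
    list(threshold = th,
         pooled = list(mse = mse(data$responses, pred),
                       mae = mae(data$responses, pred),
                       misclassification_rate = mean(cat_i != data$labels)),
         categories = cat_i, predictions = pred, folds = folds)
  })
  curve <- do.call(rbind, lapply(reports, function(rp) {
    data.frame(threshold = rp$threshold, mse = rp$pooled$mse,
               mae = rp$pooled$mae,
               misclassification_rate = rp$pooled$misclassification_rate)
  }))
  list(curve = curve, reports = reports)
}
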