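#' Majority cancer category of a leaf
#'
#' The most frequent category among the training samples in a leaf node.
#' Ties are broken toward the lowest category index, so the result is
#' deterministic; categories absent from the leaf (count 0) simply never
#' win unless all counts are 0, which cannot occur for a grown leaf.
#'
#' @param leaf a leaf node record (with a `class_counts` field).
#' @return Integer category in `1..K`.
#' @export
leaf_majority <- function(leaf) {
  if (is.null(leaf$class_counts)) stop("leaf has no class_counts")
  which.max(leaf$class_counts)
}

#' Fit a Heterogeneity Aware Random Forest
#'
#' Fits the underlying forest ([fit_forest], or [fit_mrf] when
#' `multivariate = TRUE`) and attaches the vote configuration. HARF treats
#' the cancer type of a test sample as a latent class: each tree votes the
#' majority category of the leaf the sample reaches, the sample is assigned
#' the modal vote, and the response is predicted from the agreeing trees
#' only. With a single category (K = 1) every tree always agrees and the
#' model degenerates to a plain random forest.
#'
#' @inheritParams fit_forest
#' @param vote_threshold vote fraction in (0, 1) for assigning category 1 in
#'   the two-class case; 0.5 reproduces the plain majority vote. Ignored
#'   (plain mode used) when K != 2.
#' @param multivariate grow the forest with the Mahalanobis node cost
#'   (requires `r >= 2`).
#' @param ridge see [best_split].
#' @return An object of class `harf_model` wrapping the forest.
#' @export
harf_fit <- function(data, ntree = 100L, mtry = 10L, n_size = 4L, seed = 1L,
                     vote_threshold = 0.5, multivariate = FALSE,
                     ridge = NULL) {
  stopifnot(inherits(data, "harf_data"))
  if (!is.numeric(vote_threshold) || vote_threshold <= 0 ||
      vote_threshold >= 1) {
    stop("vote_threshold must lie strictly inside (0, 1)")
  }
  forest <- if (multivariate) {
    fit_mrf(data, ntree = ntree, mtry = mtry, n_size = n_size, seed = seed,
            ridge = ridge)
  } else {
    fit_forest(data, ntree = ntree, mtry = mtry, n_size = n_size, seed = seed,
               ridge = ridge)
  }
  new_harf_model(forest, vote_threshold)
}

#' Wrap an existing forest as a HARF model
#'
#' @param forest a `harf_forest` whose leaves carry class counts.
#' @param vote_threshold see [harf_fit].
#' @return A `harf_model`.
#' @export
new_harf_model <- function(forest, vote_threshold = 0.5) {
  stopifnot(inherits(forest, "harf_forest"))
  structure(list(forest = forest, K = forest$K,
                 label_levels = forest$label_levels,
                 vote_threshold = vote_threshold),
            class = "harf_model")
}

#' @export
print.harf_model <- function(x, ...) {
  cat("<harf_model> K = ", x$K, ", vote threshold = ", x$vote_threshold,
      "\n", sep = "")
  print(x$forest)
  invisible(x)
}

# Per-tree leaf-majority votes for one sample: integer vector of length T.
tree_votes <- function(forest, x) {
  vapply(forest$trees,
         function(tr) leaf_majority(tr[[route_sample(tr, x)]]),
         integer(1L))
}

# Vote decision. For K = 2 the rule is `votes_1 / T >= threshold` (the
# boundary goes to category 1, matching the lowest-index tie-break of the
# plain mode, which this reproduces exactly at threshold 0.5). For K != 2
# the plain histogram mode is used, ties to the lowest category index.
decide_category <- function(votes, K, threshold) {
  counts <- tabulate(votes, nbins = K)
  if (K == 2L) {
    if (counts[1L] >= threshold * length(votes)) 1L else 2L
  } else {
    which.max(counts)
  }
}

#' Classify test samples from leaf-node composition
#'
#' Routes each test sample down every tree, collects the majority cancer
#' category of each reached leaf and returns the modal category. In the
#' two-class case the model's `vote_threshold` is applied to the category-1
#' vote fraction (a threshold of 0.5 is the plain majority vote).
#'
#' @param model a `harf_model`.
#' @param newx matrix of test samples (rows), or a single feature vector.
#' @return Integer vector of categories in `1..K`.
#' @export
classify_sample <- function(model, newx) {
  stopifnot(inherits(model, "harf_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  vapply(seq_len(nrow(newx)), function(i) {
    decide_category(tree_votes(model$forest, newx[i, ]), model$K,
                    model$vote_threshold)
  }, integer(1L))
}

#' HARF prediction: classify, then predict from agreeing trees
#'
#' For each test sample, the category is decided as in [classify_sample] and
#' the response is predicted using only the trees whose leaf majority (for
#' that sample) equals the decided category. The selected-tree set is never
#' empty: the modal category is voted by at least one tree; in the
#' thresholded two-class case a category decided against the raw mode can in
#' principle have no voting tree, in which case all trees are used.
#'
#' Aggregation over the selected trees defaults to the unweighted mean of
#' the reached leaf means (`"leaf_mean"`); `"weights"` pools the
#' nearest-neighbour weights of the selected trees instead.
#'
#' @param model a `harf_model`.
#' @param newx matrix of test samples (rows), or a single feature vector.
#' @param aggregate `"leaf_mean"` or `"weights"`.
#' @return List with `category` (integer vector) and `response` (matrix,
#'   samples x r).
#' @export
harf_predict <- function(model, newx, aggregate = c("leaf_mean", "weights")) {
  stopifnot(inherits(model, "harf_model"))
  aggregate <- match.arg(aggregate)
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  forest <- model$forest
  n_new <- nrow(newx)
  category <- integer(n_new)
  response <- matrix(NA_real_, n_new, forest$r,
                     dimnames = list(rownames(newx),
                                     colnames(forest$y_train)))
  for (i in seq_len(n_new)) {
    x <- newx[i, ]
    votes <- tree_votes(forest, x)
    cat_i <- decide_category(votes, model$K, model$vote_threshold)
    sel <- which(votes == cat_i)
    if (length(sel) == 0L) sel <- seq_along(votes)
    category[i] <- cat_i
    if (aggregate == "leaf_mean") {
      acc <- numeric(forest$r)
      for (t in sel) {
        tr <- forest$trees[[t]]
        acc <- acc + tr[[route_sample(tr, x)]]$mean
      }
      response[i, ] <- acc / length(sel)
    } else {
      w <- numeric(forest$n_train)
      for (t in sel) {
        tr <- forest$trees[[t]]
        leaf <- tr[[route_sample(tr, x)]]
        w[leaf$members] <- w[leaf$members] + 1 / length(leaf$members)
      }
      response[i, ] <- crossprod(w / length(sel), forest$y_train)
    }
  }
  list(category = category, response = response)
}

#' @rdname harf_predict
#' @details `mharf_predict` is the multivariate entry point; it is the same
#'   classify-then-predict rule applied to a Mahalanobis-cost forest and is
#'   provided as an explicit name for code reading clarity.
#' @export
mharf_predict <- harf_predict

#' Serialize / restore a HARF model
#'
#' JSON round-trip of the forest plus the vote configuration; see
#' [save_forest].
#'
#' @param model a `harf_model`.
#' @param path file path.
#' @return `path` (save) or the restored `harf_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "harf_model"))
  save_forest(model$forest, path)
  # append vote threshold by rewriting the document
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  doc$vote_threshold <- model$vote_threshold
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  forest <- load_forest(path)
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  new_harf_model(forest, doc$vote_threshold %||% 0.5)
}
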