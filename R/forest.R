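#' Sum-of-squares node cost
#'
#' Cost of a regression-tree node: the sum of squared differences between the
#' responses in the node and their mean, `D = sum_i (y_i - mean(y))^2`. This
#' is the quantity a CART split tries to reduce.
#'
#' @param responses non-empty numeric vector of node responses.
#' @return Non-negative scalar.
#' @examples
#' node_cost(c(1, 3)) # 2
#' @export
node_cost <- function(responses) {
  responses <- as.numeric(responses)
  if (length(responses) == 0L) stop("node_cost: empty response set")
  sum((responses - mean(responses))^2)
}

#' Cost reduction of a candidate split
#'
#' Gain of partitioning a parent node into two children:
#' `C = D(parent) - D(left) - D(right)`, which is always non-negative when
#' the children partition the parent.
#'
#' @param parent_responses,left_responses,right_responses numeric vectors;
#'   left and right must be non-empty and together contain exactly the
#'   parent's responses (as multisets).
#' @return Non-negative scalar gain.
#' @export
split_gain <- function(parent_responses, left_responses, right_responses) {
  if (length(left_responses) == 0L || length(right_responses) == 0L)
    stop("split_gain: both children must be non-empty")
  if (!isTRUE(all.equal(sort(c(left_responses, right_responses)),
                        sort(as.numeric(parent_responses))))) {
    stop("split_gain: children must partition the parent responses")
  }
  node_cost(parent_responses) - node_cost(left_responses) -
    node_cost(right_responses)
}

# Vectorised split search over candidate features.
#
# X: full feature matrix; idx: (possibly duplicated) row indices of the node;
# Z: working response matrix for those rows, in the same order as idx. For
# the sum-of-squares cost Z is the raw response; for the Mahalanobis cost it
# is the response whitened by the parent-node covariance, which reduces the
# Mahalanobis cost to a plain sum of squares in the transformed coordinates.
#
# Thresholds are the midpoints between consecutive distinct sorted feature
# values (at most k - 1 candidates). Ties in gain are broken toward the
# smallest feature index, then the smallest threshold: features are scanned
# in increasing index order and a candidate replaces the incumbent only on a
# strict improvement; within a feature which.max takes the earliest (and
# hence smallest) threshold.
best_split_rows <- function(X, idx, Z, features) {
  k <- length(idx)
  r <- ncol(Z)
  parent <- 0
  for (c in seq_len(r)) {
    zc <- Z[, c]
    parent <- parent + sum(zc * zc) - sum(zc)^2 / k
  }
  nl <- seq_len(k - 1L)
  nr <- k - nl
  best_gain <- -Inf
  best_j <- NA_integer_
  best_t <- NA_real_
  # two features can induce the same partition and hence mathematically
  # equal gains; requiring an improvement beyond float noise keeps the
  # smallest-feature-index tie rule honest
  eps <- 1e-10 * (abs(parent) + 1)
  for (j in features) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]
    ok <- xs[nl] < xs[nl + 1L]
    if (!any(ok)) next
    sse_l <- numeric(k - 1L)
    sse_r <- numeric(k - 1L)
    for (c in seq_len(r)) {
      zs <- Z[o, c]
      cs <- cumsum(zs)
      cs2 <- cumsum(zs * zs)
      sse_l <- sse_l + (cs2[nl] - cs[nl]^2 / nl)
      sse_r <- sse_r + (cs2[k] - cs2[nl]) - (cs[k] - cs[nl])^2 / nr
    }
    gain <- parent - sse_l - sse_r
    gain[!ok] <- -Inf
    p <- which.max(gain)
    if (gain[p] > best_gain + eps) {
      best_gain <- gain[p]
      best_j <- j
      best_t <- (xs[p] + xs[p + 1L]) / 2
    }
  }
  if (is.na(best_j)) return(NULL)
  list(feature = best_j, threshold = best_t, gain = max(best_gain, 0))
}

#' Best split of a node over a set of candidate features
#'
#' Scans every candidate feature and every achievable threshold (midpoints
#' between consecutive distinct sorted values) and returns the split
#' maximizing the cost reduction. With `cost = "mahalanobis"` the node
#' covariance is estimated once from `Y_node` (the parent) and child costs
#' are evaluated under that fixed covariance, so gains are comparable across
#' candidate splits.
#'
#' @param X_node numeric matrix of the node's samples (rows) x all features.
#' @param Y_node numeric matrix (or vector) of the node's responses.
#' @param features integer vector of candidate feature indices.
#' @param cost `"sse"` (univariate/summed sum of squares) or `"mahalanobis"`.
#' @param ridge ridge added to the covariance diagonal before inversion
#'   (Mahalanobis cost only); default `1e-6 * trace / r`.
#' @return `list(feature, threshold, gain)`, or `NULL` when no candidate
#'   feature admits a split into two non-empty children.
#' @export
best_split <- function(X_node, Y_node, features, cost = c("sse", "mahalanobis"),
                       ridge = NULL) {
  cost <- match.arg(cost)
  X_node <- as.matrix(X_node)
  if (is.null(dim(Y_node))) Y_node <- matrix(Y_node, ncol = 1L)
  Z <- if (cost == "mahalanobis") mahal_whiten(Y_node, ridge) else Y_node
  best_split_rows(X_node, seq_len(nrow(X_node)), Z, sort(as.integer(features)))
}

#' Grow one regression tree
#'
#' Recursive CART growth on a (possibly bootstrapped) training sample. A node
#' is split while it holds at least `n_size` samples and some candidate
#' feature admits a split with two non-empty children; at each node a fresh
#' subset of `mtry` features is drawn without replacement. Leaves store the
#' distinct original-sample indices of their members (for the
#' nearest-neighbour weight view of forest prediction), the mean response and
#' the per-category counts, the latter two computed with bootstrap
#' multiplicity since they describe the sample the tree was actually fitted
#' on.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param X full training feature matrix (n x M).
#' @param Y full training response matrix (n x r) or vector.
#' @param labels integer category vector in `1..K` (length n).
#' @param K number of categories.
#' @param mtry features drawn per node.
#' @param n_size minimum node size eligible for splitting.
#' @param boot integer vector of bootstrap-drawn row indices (duplicates
#'   allowed); default `seq_len(nrow(X))`, i.e. no bootstrap.
#' @param cost node cost, as in [best_split].
#' @param ridge see [best_split].
#' @return A tree: flat list of node records of class `harf_tree`.
#' @export
grow_tree <- function(X, Y, labels, K, mtry, n_size, boot = NULL,
                      cost = c("sse", "mahalanobis"), ridge = NULL) {
  cost <- match.arg(cost)
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  M <- ncol(X)
  if (mtry < 1L || mtry > M) stop("mtry must be in 1..", M)
  boot <- boot %||% seq_len(nrow(X))
  nodes <- vector("list", 32L)
  n_nodes <- 0L

  emit <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * n_nodes
    n_nodes
  }
  recurse <- function(rows) {
    me <- emit() # reserve slot so node ids follow pre-order
    idx <- boot[rows]
    if (length(rows) >= n_size) {
      feats <- sort(sample.int(M, mtry))
      Ynode <- Y[idx, , drop = FALSE]
      Z <- if (cost == "mahalanobis") mahal_whiten(Ynode, ridge) else Ynode
      sp <- best_split_rows(X, idx, Z, feats)
      if (!is.null(sp)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        left <- recurse(rows[go_left])
        right <- recurse(rows[!go_left])
        nodes[[me]] <<- list(leaf = FALSE, feature = sp$feature,
                             threshold = sp$threshold, left = left,
                             right = right)
        return(me)
      }
    }
    nodes[[me]] <<- list(
      leaf = TRUE,
      members = sort(unique(idx)),
      n = length(idx),
      mean = colMeans(Y[idx, , drop = FALSE]),
      class_counts = tabulate(labels[idx], nbins = K)
    )
    me
  }
  recurse(seq_along(boot))
  structure(nodes[seq_len(n_nodes)], class = "harf_tree")
}

# Index (within the flat node list) of the leaf reached by sample x.
route_sample <- function(tree, x) {
  i <- 1L
  repeat {
    nd <- tree[[i]]
    if (nd$leaf) return(i)
    i <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
  }
}

#' Construct a leaf / internal node by hand
#'
#' Building blocks for assembling small forests with known structure (worked
#' examples, unit tests). `leaf_node` describes a terminal node; `split_node`
#' an internal node whose children are themselves node descriptions. Convert
#' a nested description into a tree with [as_harf_tree].
#'
#' @param members distinct training-sample indices in the leaf.
#' @param mean leaf mean response (length r).
#' @param class_counts per-category sample counts (length K).
#' @param n total member count with bootstrap multiplicity; defaults to
#'   `sum(class_counts)`.
#' @return A node description list.
#' @export
leaf_node <- function(members, mean, class_counts, n = sum(class_counts)) {
  list(leaf = TRUE, members = as.integer(members), n = as.integer(n),
       mean = as.numeric(mean), class_counts = as.integer(class_counts))
}

#' @rdname leaf_node
#' @param feature,threshold the split.
#' @param left,right child node descriptions (nested).
#' @export
split_node <- function(feature, threshold, left, right) {
  list(leaf = FALSE, feature = as.integer(feature),
       threshold = as.numeric(threshold), left = left, right = right)
}

#' @rdname leaf_node
#' @param node a nested node description built from `leaf_node`/`split_node`.
#' @export
as_harf_tree <- function(node) {
  nodes <- list()
  count <- 0L
  flatten <- function(nd) {
    count <<- count + 1L
    me <- count
    if (isTRUE(nd$leaf)) {
      nodes[me] <<- list(nd)
    } else {
      nodes[me] <<- list(NA) # reserve pre-order slot
      nd$left <- flatten(nd$left)
      nd$right <- flatten(nd$right)
      nodes[me] <<- list(nd)
    }
    me
  }
  flatten(node)
  structure(nodes, class = "harf_tree")
}

#' Assemble a forest from explicit trees
#'
#' Wraps hand-built trees (see [leaf_node]) into a `harf_forest` so that the
#' prediction and classification machinery can run on fixtures with known
#' structure.
#'
#' @param trees list of `harf_tree` objects (or nested node descriptions).
#' @param y_train training response matrix referenced by leaf `members`.
#' @param labels integer training labels in `1..K`.
#' @param K category count; default inferred from the first leaf.
#' @param label_levels category names.
#' @return A `harf_forest`.
#' @export
manual_forest <- function(trees, y_train, labels = NULL, K = NULL,
                          label_levels = NULL) {
  trees <- lapply(trees, function(tr) {
    if (inherits(tr, "harf_tree")) tr else as_harf_tree(tr)
  })
  if (is.null(dim(y_train))) y_train <- matrix(y_train, ncol = 1L)
  first_leaf <- Filter(function(nd) nd$leaf, trees[[1L]])[[1L]]
  K <- K %||% length(first_leaf$class_counts)
  structure(list(
    trees = trees, boot = NULL,
    ntree = length(trees), mtry = NA_integer_, n_size = NA_integer_,
    seed = NA_integer_, cost = "manual", bootstrap = FALSE,
    n_train = nrow(y_train), M = NA_integer_, r = ncol(y_train), K = K,
    y_train = y_train, train_labels = labels,
    label_levels = label_levels %||% as.character(seq_len(K))
  ), class = "harf_forest")
}

#' Fit a random forest of regression trees
#'
#' Grows `ntree` un-pruned CART regression trees, each on an independent
#' bootstrap sample of the training data (size n, drawn with replacement),
#' with a fresh random subset of `mtry` features considered at every node.
#' Leaves retain the per-cancer-type composition of their training samples,
#' which is what the heterogeneity-aware classification in [harf_fit] /
#' [classify_sample] consumes.
#'
#' Reproducibility contract: the same `seed` yields the same forest. Each
#' tree draws its own RNG stream from the root seed, so the result does not
#' depend on growth order.
#'
#' @param data a [harf_data] object.
#' @param ntree number of trees (default 100).
#' @param mtry features considered per node (default 10).
#' @param n_size minimum node size eligible for splitting (default 4).
#' @param seed integer root seed.
#' @param cost `"sse"` for the univariate sum-of-squares cost, or
#'   `"mahalanobis"` for the multivariate node cost (see [fit_mrf]).
#' @param bootstrap set `FALSE` to grow every tree on the full training set
#'   (test hook; with `mtry = M` and `ntree = 1` this is a deterministic
#'   single CART fit).
#' @param ridge see [best_split].
#' @return An object of class `harf_forest`.
#' @export
fit_forest <- function(data, ntree = 100L, mtry = 10L, n_size = 4L, seed = 1L,
                       cost = c("sse", "mahalanobis"), bootstrap = TRUE,
                       ridge = NULL) {
  stopifnot(inherits(data, "harf_data"))
  cost <- match.arg(cost)
  if (ntree < 1L) stop("ntree must be >= 1")
  if (mtry < 1L || mtry > data$M) stop("mtry must be in 1..M = ", data$M)
  if (n_size < 1L) stop("n_size must be >= 1")
  n <- data$n
  tree_seeds <- spawn_seeds(seed, ntree)
  trees <- vector("list", ntree)
  boots <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    with_seed(tree_seeds[[t]], {
      boot <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[t]] <- grow_tree(data$features, data$responses, data$labels,
                              data$K, mtry, n_size, boot = boot, cost = cost,
                              ridge = ridge)
      boots[[t]] <- boot
    })
  }
  structure(list(
    trees = trees, boot = boots,
    ntree = as.integer(ntree), mtry = as.integer(mtry),
    n_size = as.integer(n_size), seed = as.integer(seed),
    cost = cost, bootstrap = bootstrap,
    n_train = n, M = data$M, r = data$r, K = data$K,
    y_train = data$responses, train_labels = data$labels,
    label_levels = data$label_levels
  ), class = "harf_forest")
}

#' @export
print.harf_forest <- function(x, ...) {
  cat("<harf_forest> ", x$ntree, " trees (cost = ", x$cost, "), ",
      x$n_train, " training samples, r = ", x$r, ", K = ", x$K, "\n", sep = "")
  invisible(x)
}

#' Per-tree prediction weights
#'
#' The nearest-neighbour view of a regression tree: the prediction for a test
#' sample is a weighted mean of the training responses, with weight
#' `1/|leaf|` on each distinct training sample in the leaf the test sample
#' reaches and 0 elsewhere. Weights are non-negative and sum to 1.
#'
#' @param tree a `harf_tree`.
#' @param x numeric feature vector of one test sample.
#' @param n_train size of the training set the tree was grown over.
#' @return Numeric weight vector of length `n_train`.
#' @export
tree_weights <- function(tree, x, n_train) {
  leaf <- tree[[route_sample(tree, x)]]
  w <- numeric(n_train)
  w[leaf$members] <- 1 / length(leaf$members)
  w
}

#' Predict responses with a fitted forest
#'
#' Two algebraically close aggregation rules are provided. `"weights"` (the
#' default) averages the per-tree nearest-neighbour weights over trees and
#' applies them to the training responses; `"leaf_mean"` averages the leaf
#' mean responses across trees. They coincide when every leaf reached has
#' equal effective size and differ only through the per-tree weight
#' normalization otherwise.
#'
#' @param forest a `harf_forest`.
#' @param newx numeric matrix of test samples (rows), or a single feature
#'   vector.
#' @param aggregate `"weights"` or `"leaf_mean"`.
#' @return Numeric matrix, test samples x r response columns.
#' @export
forest_predict <- function(forest, newx, aggregate = c("weights", "leaf_mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  out <- matrix(NA_real_, nrow(newx), forest$r,
                dimnames = list(rownames(newx), colnames(forest$y_train)))
  for (i in seq_len(nrow(newx))) {
    x <- newx[i, ]
    if (aggregate == "weights") {
      w <- numeric(forest$n_train)
      for (tr in forest$trees) {
        leaf <- tr[[route_sample(tr, x)]]
        w[leaf$members] <- w[leaf$members] + 1 / length(leaf$members)
      }
      out[i, ] <- crossprod(w / forest$ntree, forest$y_train)
    } else {
      acc <- numeric(forest$r)
      for (tr in forest$trees) {
        acc <- acc + tr[[route_sample(tr, x)]]$mean
      }
      out[i, ] <- acc / forest$ntree
    }
  }
  out
}

#' Serialize a forest to JSON
#'
#' Writes a versioned JSON document containing the growth parameters, the
#' training responses and labels (needed for weight-based prediction and
#' classification) and every node of every tree at full double precision.
#' [load_forest] restores an object whose predictions are identical.
#'
#' @param forest a `harf_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_forest <- function(forest, path) {
  doc <- list(
    format = "harf_forest", version = 1L,
    params = forest[c("ntree", "mtry", "n_size", "seed", "cost", "bootstrap",
                      "n_train", "M", "r", "K", "label_levels")],
    response_names = colnames(forest$y_train),
    y_train = forest$y_train,
    train_labels = forest$train_labels,
    trees = lapply(forest$trees, function(tr) lapply(unclass(tr), unclass))
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(doc$format, "harf_forest"))
    stop("not a harf forest document: ", path)
  p <- doc$params
  trees <- lapply(doc$trees, function(nodes) {
    structure(lapply(nodes, function(nd) {
      nd$leaf <- isTRUE(nd$leaf)
      if (nd$leaf) {
        nd$members <- as.integer(nd$members)
        nd$class_counts <- as.integer(nd$class_counts)
        nd$mean <- as.numeric(nd$mean)
      }
      nd
    }), class = "harf_tree")
  })
  y <- doc$y_train
  if (is.null(dim(y))) y <- matrix(unlist(y), ncol = p$r, byrow = TRUE)
  colnames(y) <- unlist(doc$response_names)
  structure(list(
    trees = trees, boot = NULL,
    ntree = as.integer(p$ntree), mtry = as.integer(p$mtry),
    n_size = as.integer(p$n_size), seed = as.integer(p$seed),
    cost = p$cost, bootstrap = isTRUE(p$bootstrap),
    n_train = as.integer(p$n_train), M = as.integer(p$M),
    r = as.integer(p$r), K = as.integer(p$K),
    y_train = y, train_labels = as.integer(doc$train_labels),
    label_levels = as.character(p$label_levels)
  ), class = "harf_forest")
}
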