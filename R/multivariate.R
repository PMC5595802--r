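# Default ridge: small fraction of the average response variance, plus an
# absolute floor so that constant-response nodes stay invertible.
default_ridge <- function(Lambda) {
  1e-6 * sum(diag(Lambda)) / ncol(Lambda) + 1e-12
}

# Whiten responses by the node covariance so that the Mahalanobis cost of
# any subset (under the FIXED covariance of this node) becomes an ordinary
# sum of squares in the transformed coordinates. Used during split search:
# the covariance is estimated once at the parent and reused for both
# children, keeping gains comparable across candidate splits.
mahal_whiten <- function(Y, ridge = NULL) {
  k <- nrow(Y)
  r <- ncol(Y)
  if (k < 2L || r == 1L) {
    # with one response (or a single sample) the whitening is a positive
    # scalar rescale, which cannot change the selected split; skipping it
    # keeps the univariate reduction bitwise exact, including how exact
    # gain ties between candidate features are resolved
    return(Y)
  }
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  Lambda <- crossprod(Yc) / k
  rg <- ridge %||% default_ridge(Lambda)
  A <- solve(Lambda + diag(rg, r))
  Y %*% t(chol(A))
}

#' Multivariate (Mahalanobis) node cost
#'
#' Node cost for joint multi-drug regression: the sum over node samples of
#' squared Mahalanobis distances to the node mean,
#' `D_m = sum_i (y_i - mu) Lambda^{-1} (y_i - mu)'`. By default `Lambda` is
#' the maximum-likelihood covariance of the node's responses (divide by k),
#' with a small ridge added to the diagonal before inversion since nodes can
#' hold fewer samples than response dimensions. A fixed covariance can be
#' supplied instead, which is how child costs are evaluated during split
#' search (covariance held at the parent estimate).
#'
#' With `Lambda` the identity the cost reduces to the sum over drugs of the
#' univariate sum-of-squares costs.
#'
#' @param Y_node numeric matrix (k samples x r responses) or vector.
#' @param Lambda optional fixed r x r covariance matrix; default estimated
#'   from `Y_node`.
#' @param ridge non-negative ridge added to the diagonal; default
#'   `1e-6 * trace(Lambda)/r` (plus a tiny absolute floor). Pass 0 for exact
#'   behaviour on well-conditioned fixtures.
#' @return Non-negative scalar; 0 when `k < 2` and no `Lambda` is given.
#' @export
mahalanobis_cost <- function(Y_node, Lambda = NULL, ridge = NULL) {
  if (is.null(dim(Y_node))) Y_node <- matrix(Y_node, ncol = 1L)
  Y_node <- as.matrix(Y_node)
  k <- nrow(Y_node)
  r <- ncol(Y_node)
  if (k == 0L) stop("mahalanobis_cost: empty node")
  mu <- colMeans(Y_node)
  Yc <- sweep(Y_node, 2L, mu)
  if (is.null(Lambda)) {
    if (k < 2L) return(0)
    Lambda <- crossprod(Yc) / k
    rg <- ridge %||% default_ridge(Lambda)
  } else {
    Lambda <- as.matrix(Lambda)
    rg <- ridge %||% 0
  }
  A <- solve(Lambda + diag(rg, r))
  sum((Yc %*% A) * Yc)
}

#' Fit a multivariate random forest
#'
#' Identical growth machinery to [fit_forest], with the sum-of-squares node
#' cost replaced by the Mahalanobis cost of [mahalanobis_cost]: at every node
#' the response covariance is estimated once (from the node being split) and
#' both children of each candidate split are scored under that fixed
#' covariance. Leaves store mean response vectors and per-category counts,
#' so the result supports heterogeneity-aware prediction via [harf_fit]
#' (`multivariate = TRUE`) exactly like the univariate forest.
#'
#' @inheritParams fit_forest
#' @param per_child estimate the covariance separately inside each candidate
#'   child instead of holding it fixed at the parent (configuration switch;
#'   considerably slower and ill-conditioned for small nodes).
#' @return A `harf_forest` with `cost = "mahalanobis"`.
#' @export
fit_mrf <- function(data, ntree = 100L, mtry = 10L, n_size = 4L, seed = 1L,
                    bootstrap = TRUE, ridge = NULL, per_child = FALSE) {
  stopifnot(inherits(data, "harf_data"))
  if (data$r < 2L) stop("fit_mrf requires r >= 2 response columns; ",
                        "use fit_forest for a single drug")
  if (per_child) {
    fit_forest_per_child(data, ntree, mtry, n_size, seed, ridge)
  } else {
    fit_forest(data, ntree = ntree, mtry = mtry, n_size = n_size, seed = seed,
               cost = "mahalanobis", bootstrap = bootstrap, ridge = ridge)
  }
}

# Per-child covariance variant: exhaustive split scoring with the covariance
# re-estimated inside every candidate child. Quadratic in node size; meant
# for small studies of the covariance convention, not routine fitting.
fit_forest_per_child <- function(data, ntree, mtry, n_size, seed, ridge) {
  n <- data$n
  tree_seeds <- spawn_seeds(seed, ntree)
  trees <- vector("list", ntree)
  boots <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    with_seed(tree_seeds[[t]], {
      boot <- sample.int(n, n, replace = TRUE)
      trees[[t]] <- grow_tree_per_child(data$features, data$responses,
                                        data$labels, data$K, mtry, n_size,
                                        boot, ridge)
      boots[[t]] <- boot
    })
  }
  structure(list(
    trees = trees, boot = boots,
    ntree = as.integer(ntree), mtry = as.integer(mtry),
    n_size = as.integer(n_size), seed = as.integer(seed),
    cost = "mahalanobis_per_child", bootstrap = TRUE,
    n_train = n, M = data$M, r = data$r, K = data$K,
    y_train = data$responses, train_labels = data$labels,
    label_levels = data$label_levels
  ), class = "harf_forest")
}

grow_tree_per_child <- function(X, Y, labels, K, mtry, n_size, boot, ridge) {
  M <- ncol(X)
  nodes <- list()
  count <- 0L
  recurse <- function(rows) {
    count <<- count + 1L
    me <- count
    nodes[me] <<- list(NA)
    idx <- boot[rows]
    k <- length(rows)
    if (k >= n_size) {
      feats <- sort(sample.int(M, mtry))
      Ynode <- Y[idx, , drop = FALSE]
      parent_cost <- mahalanobis_cost(Ynode, ridge = ridge)
      best <- NULL
      best_gain <- -Inf
      for (j in feats) {
        x <- X[idx, j]
        cuts <- sort(unique(x))
        if (length(cuts) < 2L) next
        mids <- (cuts[-length(cuts)] + cuts[-1L]) / 2
        for (z in mids) {
          l <- x <= z
          gain <- parent_cost -
            mahalanobis_cost(Ynode[l, , drop = FALSE], ridge = ridge) -
            mahalanobis_cost(Ynode[!l, , drop = FALSE], ridge = ridge)
          if (gain > best_gain) {
            best_gain <- gain
            best <- list(feature = j, threshold = z)
          }
        }
      }
      if (!is.null(best)) {
        go_left <- X[idx, best$feature] <= best$threshold
        l <- recurse(rows[go_left])
        r <- recurse(rows[!go_left])
        nodes[me] <<- list(list(leaf = FALSE, feature = best$feature,
                                threshold = best$threshold, left = l,
                                right = r))
        return(me)
      }
    }
    nodes[me] <<- list(list(
      leaf = TRUE, members = sort(unique(idx)), n = k,
      mean = colMeans(Y[idx, , drop = FALSE]),
      class_counts = tabulate(labels[idx], nbins = K)
    ))
    me
  }
  recurse(seq_along(boot))
  structure(nodes, class = "harf_tree")
}
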