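#' Idealized tree-vote model
#'
#' Parameters of the theoretical model of HARF's classification stage: T
#' trees vote independently, a tree votes the correct category with
#' probability `b0` (for true class 0) or `b1` (for true class 1), and class
#' 0 has prior probability `prior0`. The number of class-0 votes is then
#' binomial under either truth, which yields a closed-form Bayes vote
#' threshold and Bayes error.
#'
#' @param b0 probability a tree votes 0 when the truth is 0, in (0, 1).
#' @param b1 probability a tree votes 1 when the truth is 1, in (0, 1).
#' @param prior0 prior probability of class 0, in (0, 1).
#' @param ntree number of trees T.
#' @return An object of class `vote_model`.
#' @export
vote_model <- function(b0, b1, prior0 = 0.5, ntree = 100L) {
  for (p in c(b0 = b0, b1 = b1, prior0 = prior0)) {
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("b0, b1 and prior0 must lie strictly inside (0, 1)")
  }
  if (ntree < 1L) stop("ntree must be >= 1")
  structure(list(b0 = b0, b1 = b1, prior0 = prior0,
                 ntree = as.integer(ntree)),
            class = "vote_model")
}

#' @export
print.vote_model <- function(x, ...) {
  cat("<vote_model> b0 = ", x$b0, ", b1 = ", x$b1, ", P(Y=0) = ", x$prior0,
      ", T = ", x$ntree, "\n", sep = "")
  invisible(x)
}

#' Bayes vote threshold
#'
#' The closed-form count threshold of the Bayes classifier for the vote
#' model: with `beta0 = b0*b1 / ((1-b0)(1-b1))` and `beta1 = b1/(1-b0)`, the
#' optimal rule declares class 0 exactly when the number of class-0 votes k
#' satisfies `k > That` with
#' `That = T log(beta1)/log(beta0) + log((1-C)/C)/log(beta0)`. In the
#' symmetric case `b0 = b1`, `C = 1/2` this is the plain majority rule
#' `k > T/2`; an unbalanced prior shifts the threshold below or above 50%.
#'
#' @param vm a [vote_model].
#' @return The (generally non-integer) threshold `That`.
#' @export
vote_threshold <- function(vm) {
  stopifnot(inherits(vm, "vote_model"))
  beta0 <- vm$b0 * vm$b1 / ((1 - vm$b0) * (1 - vm$b1))
  if (abs(log(beta0)) < .Machine$double.eps * 4) {
    stop("degenerate classifier: b0*b1 == (1-b0)*(1-b1), the votes carry ",
         "no information about the class")
  }
  beta1 <- vm$b1 / (1 - vm$b0)
  vm$ntree * log(beta1) / log(beta0) +
    log((1 - vm$prior0) / vm$prior0) / log(beta0)
}

#' Bayes error of the tree-vote classifier
#'
#' Minimal misclassification probability of the vote model: for each vote
#' count k the Bayes rule picks the class with the larger posterior mass, so
#' the error sums the smaller of the two joint probabilities,
#' `sum_k min(C P(B=k|Y=0), (1-C) P(B=k|Y=1))` with `B|Y=0 ~ Bin(T, b0)` and
#' `B|Y=1 ~ Bin(T, 1-b1)`. This equals the two binomial tail sums on either
#' side of the [vote_threshold] whenever that threshold is well defined
#' (ties at an integer threshold go to class 1, the `<=` branch of the Bayes
#' rule), and remains defined in the degenerate uninformative case where
#' the threshold is not.
#'
#' @param vm a [vote_model].
#' @return Error probability in \[0, 1\].
#' @export
bayes_error <- function(vm) {
  stopifnot(inherits(vm, "vote_model"))
  k <- 0:vm$ntree
  joint0 <- vm$prior0 * stats::dbinom(k, vm$ntree, vm$b0)
  joint1 <- (1 - vm$prior0) * stats::dbinom(k, vm$ntree, 1 - vm$b1)
  sum(pmin(joint0, joint1))
}

#' Estimate per-tree vote accuracies from a fitted model
#'
#' Empirical plug-in estimates of the vote-model accuracies `b0`, `b1`: the
#' fraction, over (tree, sample) pairs whose sample truly belongs to class
#' c, of leaf-majority votes equal to c. By default all training samples are
#' routed through all trees (in-bag, following the use of training-sample
#' responses on the initially generated trees); `oob = TRUE` restricts each
#' tree's tally to the samples outside its bootstrap.
#'
#' Estimates are clipped into `[1/(2TS), 1 - 1/(2TS)]` (S = samples used) so
#' they always form a valid [vote_model].
#'
#' @param model a two-class `harf_model` (or `harf_forest`).
#' @param data the [harf_data] to vote on; defaults to the training data
#'   stored in the forest (features are required, so pass the training set
#'   explicitly when the forest was restored from JSON).
#' @param oob use only out-of-bag (tree, sample) pairs.
#' @return Named numeric vector `c(b0 = ..., b1 = ...)`.
#' @export
estimate_tree_accuracies <- function(model, data, oob = FALSE) {
  forest <- if (inherits(model, "harf_model")) model$forest else model
  stopifnot(inherits(forest, "harf_forest"), inherits(data, "harf_data"))
  if (forest$K != 2L) stop("the vote theory is binary: model must have K = 2")
  if (oob && is.null(forest$boot))
    stop("out-of-bag estimation needs the stored bootstrap indices")
  votes_ok <- matrix(NA, forest$ntree, data$n)
  for (t in seq_len(forest$ntree)) {
    tr <- forest$trees[[t]]
    inbag <- if (oob) unique(forest$boot[[t]]) else integer()
    for (i in seq_len(data$n)) {
      if (oob && i <= forest$n_train && i %in% inbag) next
      v <- leaf_majority(tr[[route_sample(tr, data$features[i, ])]])
      votes_ok[t, i] <- (v == data$labels[i])
    }
  }
  S <- data$n
  lo <- 1 / (2 * forest$ntree * S)
  est <- vapply(1:2, function(cls) {
    m <- votes_ok[, data$labels == cls, drop = FALSE]
    mean(m, na.rm = TRUE)
  }, numeric(1L))
  est <- pmin(pmax(est, lo), 1 - lo)
  c(b0 = est[1L], b1 = est[2L])
}
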