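# Independent brute-force oracles used to pin expected values.

# Exhaustive split search: every candidate feature, every midpoint between
# consecutive distinct values, gains via plain node costs. Same tie rule as
# the implementation (smallest feature index, then smallest threshold).
brute_best_split <- function(X, Y, features) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  col_cost <- function(rows) {
    sum(vapply(seq_len(ncol(Y)),
               function(c) node_cost(Y[rows, c]), numeric(1L)))
  }
  parent <- col_cost(seq_len(nrow(X)))
  best <- NULL
  best_gain <- -Inf
  for (j in sort(features)) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2L) next
    mids <- (xs[-length(xs)] + xs[-1L]) / 2
    for (z in mids) {
      left <- which(X[, j] <= z)
      gain <- parent - col_cost(left) - col_cost(setdiff(seq_len(nrow(X)), left))
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(feature = j, threshold = z, gain = gain)
      }
    }
  }
  best
}

# All 2^n - 2 bipartitions of a response vector, as a list of left index sets.
all_bipartitions <- function(n) {
  out <- list()
  for (size in 1:(n - 1L)) {
    sets <- utils::combn(n, size, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

# Bayes error of the vote model by enumerating all 2^T vote outcomes:
# each tree votes category 0 with probability b0 (truth 0) or 1 - b1
# (truth 1); outcomes are pooled by their zero-vote count and the Bayes
# decision compares the summed joint probabilities.
enum_bayes_error <- function(b0, b1, prior0, T) {
  outcomes <- as.matrix(expand.grid(rep(list(c(0L, 1L)), T)))
  B <- rowSums(outcomes == 0L)
  p0 <- apply(outcomes, 1L, function(v) prod(ifelse(v == 0L, b0, 1 - b0)))
  p1 <- apply(outcomes, 1L, function(v) prod(ifelse(v == 0L, 1 - b1, b1)))
  err <- 0
  for (k in unique(B)) {
    j0 <- prior0 * sum(p0[B == k])
    j1 <- (1 - prior0) * sum(p1[B == k])
    err <- err + min(j0, j1)
  }
  err
}
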