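# Hand-built forests with known structure, plus small random datasets.

# Three single-leaf trees whose leaf majorities are (A, B, A) and whose leaf
# means are (13.67, 20, 11.67): the classic classify-then-average toy.
fig2_model <- function() {
  trees <- list(
    leaf_node(members = 1:3, mean = 13.67, class_counts = c(2L, 1L)),
    leaf_node(members = 4:5, mean = 20.00, class_counts = c(0L, 2L)),
    leaf_node(members = c(1L, 4L, 6L), mean = 11.67, class_counts = c(2L, 1L))
  )
  y <- c(14, 13, 14, 20, 20, 11)
  f <- manual_forest(trees, y_train = y, K = 2L,
                     label_levels = c("C_A", "C_B"))
  new_harf_model(f, vote_threshold = 0.5)
}

# 100 single-leaf trees: 70 lean to category 1 with leaf mean 0.25, 30 lean
# to category 2 with leaf mean 0.50. Every leaf holds one distinct training
# sample whose response equals the leaf mean, so both aggregation rules give
# the same arithmetic.
seventy_thirty_model <- function() {
  y <- c(rep(0.25, 70), rep(0.50, 30))
  trees <- lapply(1:100, function(i) {
    leaf_node(members = i, mean = y[i],
              class_counts = if (i <= 70) c(1L, 0L) else c(0L, 1L))
  })
  f <- manual_forest(trees, y_train = y, K = 2L,
                     label_levels = c("C_A", "C_B"))
  new_harf_model(f, vote_threshold = 0.5)
}

# Small random regression dataset (balanced labels, no structure).
toy_data <- function(n = 20L, M = 5L, r = 1L, K = 2L, seed = 1L) {
  stopifnot(n %% K == 0L)
  set.seed(seed)
  harf_data(matrix(rnorm(n * M), n, M),
            matrix(runif(n * r), n, r),
            rep(LETTERS[seq_len(K)], each = n %/% K))
}

# Default-condition synthetic cohort, optionally resized.
sep_cohort <- function(seed, n_per_class = c(25L, 25L), ...) {
  make_dataset(sim_config(n_per_class = n_per_class, ...), seed = seed)
}
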