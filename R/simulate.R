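#' Configuration of the two-class synthetic cohort
#'
#' Parameters of the pathway-inspired simulator used throughout the test
#' surface. Each synthetic cell line is a block of kinases connected in
#' parallel: up to `max_targets` distinct kinases are drawn from a pool of
#' `n_targets_pool`, with the draw biased toward the low-index end of the
#' pool for cancer type 1 (left-truncated standard normal, floored) and
#' toward the high-index end for cancer type 2 (right-truncated normal at
#' the top of the pool, i.e. the mirror image). Sensitivity to a drug is the
#' drug's weakest inhibition over the cell line's kinases, scaled by a
#' uniform cell-line potency variable. Expression for `n_genes` genes starts
#' from a shared beta-distributed base value per gene; type-1 samples have
#' `n_marker_genes` marker genes shifted up by N(`shift_mean`,
#' `shift_sd`^2), type-2 samples have a down-regulated gene set shifted down
#' by the same law, and every entry receives N(0, `noise_sd`^2) noise.
#'
#' @param n_per_class integer vector of per-class sample counts (default
#'   `c(25, 25)`).
#' @param n_targets_pool kinase pool size (default 10).
#' @param max_targets maximum distinct kinases per cell line (default 5).
#' @param drug_inhibition numeric vector of length `n_targets_pool` in
#'   \[0, 1\] (or a matrix with one column per drug for multivariate
#'   responses): normalized inhibition of each kinase by the drug. The
#'   default profile fully inhibits the low-index half of the pool (the
#'   drug's primary targets) and weakly inhibits the high-index half
#'   (off-target activity, 5/17); together with the default potency range
#'   this places the class mean sensitivities at 0.85 and 0.25, the
#'   canonical well-separated two-type study.
#' @param potency_range range of the uniform cell-line potency scale `b`
#'   (default `c(0.7, 1)`, mean potency 0.85; set `c(0, 1)` for a fully
#'   diffuse potency, which halves the attainable class means and roughly
#'   tenfolds the within-class response variance).
#' @param n_genes simulated genes (default 100).
#' @param n_marker_genes genes up-shifted in class 1 (default 10).
#' @param shift_mean,shift_sd mean and standard deviation of the class
#'   expression shift (defaults 1.25 and 0.5).
#' @param noise_sd standard deviation of the additive expression noise
#'   (default 0.4).
#' @param base_expr_shape two beta shape parameters for the per-gene base
#'   expression (default `c(2, 2)`).
#' @param base_expr_scale base expression is scaled to
#'   \[0, `base_expr_scale`\] (default 10).
#' @param down_set which genes are down-shifted in class 2: `"rest"` (all
#'   non-marker genes, the default), `"ten"` (a disjoint set of
#'   `n_marker_genes` genes), or `"none"`.
#' @param class_means optional length-2 vector; when given, each class's
#'   sensitivities are rescaled so its sample mean matches (for studying
#'   response-gap and class-imbalance effects).
#' @param max_draws cap on kinase draws per cell line while collecting
#'   distinct targets (default 20).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(25L, 25L), n_targets_pool = 10L,
                       max_targets = 5L,
                       drug_inhibition = NULL, potency_range = c(0.7, 1),
                       n_genes = 100L, n_marker_genes = 10L,
                       shift_mean = 1.25, shift_sd = 0.5, noise_sd = 0.4,
                       base_expr_shape = c(2, 2), base_expr_scale = 10,
                       down_set = c("rest", "ten", "none"),
                       class_means = NULL, max_draws = 20L) {
  down_set <- match.arg(down_set)
  if (is.null(drug_inhibition)) {
    half <- floor(n_targets_pool / 2)
    drug_inhibition <- c(rep(1, half), rep(5 / 17, n_targets_pool - half))
  }
  if (length(potency_range) != 2L || any(potency_range < 0) ||
      any(potency_range > 1) || potency_range[1L] > potency_range[2L])
    stop("potency_range must be an increasing pair inside [0, 1]")
  if (is.null(dim(drug_inhibition)))
    drug_inhibition <- matrix(drug_inhibition, ncol = 1L)
  if (nrow(drug_inhibition) != n_targets_pool)
    stop("drug_inhibition must have one row per kinase in the pool")
  if (any(drug_inhibition < 0 | drug_inhibition > 1))
    stop("inhibition values must lie in [0, 1]")
  if (max_targets < 1L || max_targets > n_targets_pool)
    stop("max_targets must be in 1..n_targets_pool")
  if (shift_sd <= 0 || noise_sd < 0) stop("spreads must be positive")
  if (length(n_per_class) != 2L || any(n_per_class < 0L))
    stop("n_per_class must be two non-negative counts")
  if (down_set == "ten" && 2L * n_marker_genes > n_genes)
    stop("not enough genes for a disjoint down-regulated set")
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_targets_pool = as.integer(n_targets_pool),
    max_targets = as.integer(max_targets),
    drug_inhibition = drug_inhibition,
    potency_range = potency_range,
    n_genes = as.integer(n_genes),
    n_marker_genes = as.integer(n_marker_genes),
    shift_mean = shift_mean, shift_sd = shift_sd, noise_sd = noise_sd,
    base_expr_shape = base_expr_shape, base_expr_scale = base_expr_scale,
    down_set = down_set, class_means = class_means,
    max_draws = as.integer(max_draws)
  ), class = "sim_config")
}

#' Draw a cell line's kinase target set
#'
#' Draws distinct kinase indices (1-based, in `1..n_targets_pool`) until
#' `max_targets` distinct kinases are collected or the draw cap is reached.
#' Class 1 uses a left-truncated standard normal measured from the bottom of
#' the pool, so index 1 is the most frequent target; class 2 uses its mirror
#' image (a right-truncated normal anchored at the top of the pool), so the
#' highest index dominates. Continuous draws are mapped to indices by
#' flooring the distance from the favored end of the pool, which preserves
#' the stated bias direction and keeps the most probable index at the
#' anchor.
#'
#' Uses the current RNG state.
#'
#' @param config a [sim_config].
#' @param class_id 1 or 2.
#' @return Integer vector of 1 to `max_targets` distinct kinase indices.
#' @export
draw_targets <- function(config, class_id) {
  stopifnot(inherits(config, "sim_config"), class_id %in% 1:2)
  nt <- config$n_targets_pool
  phi <- integer(0L)
  for (d in seq_len(config$max_draws)) {
    z <- abs(stats::rnorm(1L)) # half-normal = truncated N(0,1)
    idx <- if (class_id == 1L) {
      min(floor(z) + 1L, nt)
    } else {
      max(nt - floor(z), 1L)
    }
    phi <- union(phi, as.integer(idx))
    if (length(phi) >= config$max_targets) break
  }
  sort(phi)
}

#' Simulated drug sensitivity of a cell line
#'
#' Target-inhibition-map sensitivity: the drug's effect on a parallel block
#' of kinases is limited by its weakest inhibition among the kinases
#' present, so the sensitivity is `b * min(inhibition over phi /\\ targets)`
#' with `b` a uniform cell-line potency scale drawn from
#' `config$potency_range`. When the drug inhibits none of the cell line's
#' kinases the sensitivity is 0.
#'
#' @param config a [sim_config].
#' @param phi integer vector of the cell line's kinase indices.
#' @param b optional fixed potency in \[0, 1\] (test hook); default a fresh
#'   uniform draw from the current RNG state.
#' @param drug which drug column of `drug_inhibition` to use.
#' @return Sensitivity in \[0, 1\].
#' @export
sensitivity <- function(config, phi, b = NULL, drug = 1L) {
  stopifnot(inherits(config, "sim_config"), length(phi) >= 1L)
  inh <- config$drug_inhibition[, drug]
  targets <- which(inh > 0)
  shared <- intersect(as.integer(phi), targets)
  if (length(shared) == 0L) return(0)
  b <- b %||% stats::runif(1L, config$potency_range[1L],
                           config$potency_range[2L])
  b * min(inh[shared])
}

#' Simulate the expression matrix
#'
#' Every gene gets a base expression shared by all samples (beta-distributed,
#' scaled); marker genes are up-shifted in class-1 samples and the
#' configured down-set is down-shifted in class-2 samples, each by an
#' independent N(`shift_mean`, `shift_sd`^2) draw per entry; finally every
#' entry receives independent N(0, `noise_sd`^2) noise.
#'
#' Uses the current RNG state.
#'
#' @param config a [sim_config].
#' @param class_ids integer vector (1 or 2) giving each sample's class.
#' @return Numeric matrix, samples x `n_genes`.
#' @export
simulate_expression <- function(config, class_ids) {
  stopifnot(inherits(config, "sim_config"), all(class_ids %in% 1:2))
  n <- length(class_ids)
  G <- config$n_genes
  base <- config$base_expr_scale *
    stats::rbeta(G, config$base_expr_shape[1L], config$base_expr_shape[2L])
  E <- matrix(base, n, G, byrow = TRUE)
  markers <- seq_len(config$n_marker_genes)
  down <- switch(config$down_set,
    rest = setdiff(seq_len(G), markers),
    ten = config$n_marker_genes + seq_len(config$n_marker_genes),
    none = integer(0L)
  )
  i1 <- which(class_ids == 1L)
  i2 <- which(class_ids == 2L)
  if (length(i1) && length(markers)) {
    E[i1, markers] <- E[i1, markers] +
      stats::rnorm(length(i1) * length(markers), config$shift_mean,
                   config$shift_sd)
  }
  if (length(i2) && length(down)) {
    E[i2, down] <- E[i2, down] -
      stats::rnorm(length(i2) * length(down), config$shift_mean,
                   config$shift_sd)
  }
  if (config$noise_sd > 0) {
    E <- E + stats::rnorm(n * G, 0, config$noise_sd)
  }
  colnames(E) <- paste0("G", seq_len(G))
  E
}

#' Generate a complete synthetic cohort
#'
#' Draws kinase target sets, sensitivities (one response column per drug
#' profile) and expression for `n_per_class` cell lines per cancer type and
#' assembles them into an aligned [harf_data] (a class with zero samples is
#' dropped, so `n_per_class = c(0, 25)` yields a one-type cohort). When
#' `config$class_means` is set, each class's response columns are rescaled
#' to match the requested class means.
#'
#' @param config a [sim_config].
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @return A [harf_data] with an extra attribute `targets` (the per-sample
#'   kinase sets).
#' @export
make_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    class_ids <- rep(1:2, times = config$n_per_class)
    n <- length(class_ids)
    if (n == 0L) stop("empty cohort: n_per_class sums to zero")
    r <- ncol(config$drug_inhibition)
    phis <- lapply(class_ids, function(cl) draw_targets(config, cl))
    Y <- matrix(0, n, r)
    for (i in seq_len(n)) {
      for (d in seq_len(r)) {
        Y[i, d] <- sensitivity(config, phis[[i]], drug = d)
      }
    }
    if (!is.null(config$class_means)) {
      for (cl in 1:2) {
        rows <- which(class_ids == cl)
        if (!length(rows)) next
        for (d in seq_len(r)) {
          cur <- mean(Y[rows, d])
          if (cur > 0) Y[rows, d] <- Y[rows, d] * config$class_means[cl] / cur
        }
      }
    }
    E <- simulate_expression(config, class_ids)
    colnames(Y) <- paste0("drug_", seq_len(r))
    labels <- c("type1", "type2")[class_ids]
    d <- harf_data(E, Y, labels,
                   sample_ids = sprintf("CL%03d", seq_len(n)))
    attr(d, "targets") <- phis
    d
  })
}
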