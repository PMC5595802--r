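#' Assemble an aligned drug-sensitivity dataset
#'
#' Bundles an expression matrix, a response matrix (normalized dose-response
#' AUC values; one column per drug) and a per-sample cancer-type label into a
#' single validated object. Rows of all components refer to the same samples
#' in the same order. Labels are stored as contiguous integer categories
#' `1..K`, assigned in lexicographic order of the original label strings so
#' that category indexing (and hence tie-breaking downstream) is
#' deterministic.
#'
#' Categories that occur zero times (e.g. after aligning files that cover
#' different samples) are dropped from the level set with a warning, so `K`
#' always counts categories that are actually present. Missing values are
#' refused: modelling code assumes complete data and imputation is out of
#' scope.
#'
#' @param features numeric matrix, samples x genes.
#' @param responses numeric matrix or vector, samples x drugs (a vector is a
#'   single drug).
#' @param labels character or factor vector of cancer-type labels, one per
#'   sample.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to rownames of `features` or `S1..Sn`.
#' @param feature_ids character vector of feature identifiers; defaults to
#'   colnames of `features` or `G1..Gm`.
#' @return An object of class `harf_data`: a list with elements `features`,
#'   `responses`, `labels` (integer in `1..K`), `label_levels`, `sample_ids`,
#'   `feature_ids`, `n`, `M`, `r`, `K`.
#' @examples
#' d <- harf_data(matrix(rnorm(12), 3), runif(3), c("A", "A", "B"))
#' d$K
#' @export
harf_data <- function(features, responses, labels, sample_ids = NULL,
                      feature_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(dim(responses))) responses <- matrix(responses, ncol = 1L)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  n <- nrow(features)
  if (nrow(responses) != n || length(labels) != n) {
    stop("features, responses and labels must have one row per sample ",
         "(got ", n, ", ", nrow(responses), ", ", length(labels), ")")
  }
  if (anyNA(features) || anyNA(responses) || anyNA(labels)) {
    stop("missing values are not supported; remove or complete the ",
         "offending samples before loading")
  }
  sample_ids <- sample_ids %||% rownames(features) %||% paste0("S", seq_len(n))
  feature_ids <- feature_ids %||% colnames(features) %||%
    paste0("G", seq_len(ncol(features)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  labels <- as.character(labels)
  levels_all <- sort(unique(labels))
  lab_int <- match(labels, levels_all)
  present <- sort(unique(lab_int))
  if (length(present) < length(levels_all)) {
    # cannot happen via match() on its own input, but can when a caller
    # passes a factor with unused levels through as.character -- keep the
    # recount logic in one place
    levels_all <- levels_all[present]
    lab_int <- match(labels, levels_all)
  }
  rownames(features) <- sample_ids
  colnames(features) <- feature_ids
  rownames(responses) <- sample_ids
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("response_", seq_len(ncol(responses)))
  structure(list(
    features = features, responses = responses,
    labels = lab_int, label_levels = levels_all,
    sample_ids = sample_ids, feature_ids = feature_ids,
    n = n, M = ncol(features), r = ncol(responses), K = length(levels_all)
  ), class = "harf_data")
}

#' @export
print.harf_data <- function(x, ...) {
  cat("<harf_data> ", x$n, " samples x ", x$M, " features, ",
      x$r, if (x$r == 1L) " drug, " else " drugs, ",
      x$K, " cancer type(s): ",
      paste(x$label_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Read one CSV with a sample_id first column; every remaining column must be
# numeric. Reports the first offending cell on failure.
read_sample_csv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(what, " file must have a sample_id column plus data: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in ", what, " file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  df
}

check_numeric_cols <- function(df, what) {
  for (j in 2:ncol(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      stop("non-numeric value ", dQuote(col[bad]), " in ", what,
           " file at row ", bad, ", column ", dQuote(names(df)[j]))
    }
    if (anyNA(col)) {
      stop("missing value in ", what, " file at row ", which(is.na(col))[1L],
           ", column ", dQuote(names(df)[j]))
    }
  }
  df
}

#' Load a dataset from a CSV triplet
#'
#' Reads the three delimited files (expression features, drug responses,
#' cancer-type labels) and aligns them by the `sample_id` key in the first
#' column of each file -- row order in the files is irrelevant. The features
#' and responses files must cover exactly the same samples; the labels file
#' must cover at least those samples (extra rows are ignored). Any label
#' category left without samples after alignment is dropped with a warning.
#'
#' All files are comma-delimited with a mandatory header row and the sample
#' id in the first column.
#'
#' @param features_path CSV of samples x genes.
#' @param responses_path CSV of samples x drugs.
#' @param labels_path CSV with columns `sample_id,label`.
#' @return A [harf_data] object.
#' @export
load_dataset <- function(features_path, responses_path, labels_path) {
  fx <- check_numeric_cols(read_sample_csv(features_path, "features"), "features")
  ry <- check_numeric_cols(read_sample_csv(responses_path, "responses"), "responses")
  lb <- read_sample_csv(labels_path, "labels")

  fid <- as.character(fx[[1L]])
  rid <- as.character(ry[[1L]])
  lid <- as.character(lb[[1L]])
  miss_r <- setdiff(fid, rid)
  extra_r <- setdiff(rid, fid)
  if (length(miss_r) || length(extra_r)) {
    stop("sample ids do not align between features and responses files; ",
         if (length(miss_r)) paste0("missing from responses: ",
                                    paste(miss_r, collapse = ", "), "; "),
         if (length(extra_r)) paste0("missing from features: ",
                                     paste(extra_r, collapse = ", ")))
  }
  miss_l <- setdiff(fid, lid)
  if (length(miss_l)) {
    stop("sample ids missing from labels file: ",
         paste(miss_l, collapse = ", "))
  }
  X <- as.matrix(fx[, -1L, drop = FALSE])
  Y <- as.matrix(ry[match(fid, rid), -1L, drop = FALSE])
  labs <- as.character(lb[[2L]])[match(fid, lid)]
  if (anyNA(labs)) stop("missing label value for: ",
                        paste(fid[is.na(labs)], collapse = ", "))
  all_levels <- sort(unique(as.character(lb[[2L]])))
  used_levels <- sort(unique(labs))
  if (length(dropped <- setdiff(all_levels, used_levels))) {
    warning("dropping label categories with no aligned samples: ",
            paste(dropped, collapse = ", "))
  }
  harf_data(X, Y, labs, sample_ids = fid,
            feature_ids = colnames(fx)[-1L])
}

#' Write predictions to CSV
#'
#' One row per sample with columns `sample_id`, `category` (the inferred
#' cancer type, `NA` for models that do not classify) and
#' `response_1..response_r`. Values are written at full double precision so
#' that a round-trip read reproduces them.
#'
#' @param sample_ids character vector.
#' @param predicted_categories vector of category labels (or `NA`).
#' @param predicted_responses numeric matrix or vector, one row per sample.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_predictions <- function(sample_ids, predicted_categories,
                             predicted_responses, path) {
  if (is.null(dim(predicted_responses)))
    predicted_responses <- matrix(predicted_responses, ncol = 1L)
  n <- length(sample_ids)
  if (length(predicted_categories) != n || nrow(predicted_responses) != n) {
    stop("sample_ids, predicted_categories and predicted_responses must ",
         "have equal lengths")
  }
  out <- data.frame(sample_id = as.character(sample_ids),
                    category = as.character(predicted_categories),
                    stringsAsFactors = FALSE)
  resp <- as.data.frame(predicted_responses)
  names(resp) <- paste0("response_", seq_len(ncol(resp)))
  out <- cbind(out, resp)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dataset to a CSV triplet
#'
#' Inverse of [load_dataset]: writes `<prefix>_features.csv`,
#' `<prefix>_responses.csv` and `<prefix>_labels.csv`.
#'
#' @param data a [harf_data] object.
#' @param prefix path prefix for the three files.
#' @return Named character vector of the three paths, invisibly.
#' @export
save_dataset <- function(data, prefix) {
  stopifnot(inherits(data, "harf_data"))
  paths <- c(features = paste0(prefix, "_features.csv"),
             responses = paste0(prefix, "_responses.csv"),
             labels = paste0(prefix, "_labels.csv"))
  fdf <- data.frame(sample_id = data$sample_ids, data$features,
                    check.names = FALSE)
  rdf <- data.frame(sample_id = data$sample_ids, data$responses,
                    check.names = FALSE)
  ldf <- data.frame(sample_id = data$sample_ids,
                    label = data$label_levels[data$labels])
  for (nm in names(paths)) {
    df <- switch(nm, features = fdf, responses = rdf, labels = ldf)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
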