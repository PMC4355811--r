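#' Construct a labeled expression dataset
#'
#' Bundles a samples x features numeric matrix with integer class labels and
#' identifiers. Class labels are recoded to consecutive integers `1..c`
#' (in order of first appearance of the sorted unique user labels) and the
#' mapping is retained so predictions can be decoded back to the original
#' labels.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels, one per row of `x`; any atomic type.
#' @param sample_ids,feature_ids optional character identifiers; defaults are
#'   taken from `dimnames(x)` or generated.
#' @return an object of class `labeled_dataset` with elements `matrix`,
#'   `labels` (integer `1..c`), `sample_ids`, `feature_ids`, `label_map`
#'   (character vector: original label of each class code).
#' @examples
#' d <- labeled_dataset(matrix(rnorm(12), 4, 3), c("A", "A", "B", "B"))
#' d$labels        # 1 1 2 2
#' d$label_map     # "A" "B"
#' @export
labeled_dataset <- function(x, labels, sample_ids = NULL, feature_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) != length(labels)) {
    stop("number of rows of the matrix (", nrow(x), ") must equal the number of labels (",
         length(labels), ")")
  }
  if (anyNA(x)) stop("expression matrix contains missing values; impute or drop them before loading")
  if (anyNA(labels)) stop("labels contain missing values")
  lev <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), lev)
  cnt <- tabulate(y, nbins = length(lev))
  if (any(cnt < 2)) {
    stop("class with fewer than 2 samples: ", paste(lev[cnt < 2], collapse = ", "),
         "; stratified splitting needs at least 2 samples per class")
  }
  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(feature_ids)) feature_ids <- colnames(x)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(x)))
  dimnames(x) <- list(sample_ids, feature_ids)
  structure(
    list(matrix = x, labels = y, sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids), label_map = lev),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$matrix), "samples x", ncol(x$matrix), "features,",
      length(x$label_map), "classes\n")
  cnt <- tabulate(x$labels, nbins = length(x$label_map))
  cat("  classes:", paste0(x$label_map, " (n=", cnt, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Number of classes in a labeled dataset
#' @param data a `labeled_dataset`.
#' @return integer class count.
#' @export
n_classes <- function(data) length(data$label_map)

detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (lengths(regmatches(line1, gregexpr("\t", line1))) > 0) "\t" else ","
}

#' Read a labeled expression table from delimited text
#'
#' Reads a CSV/TSV table (separator auto-detected from the header row) in one
#' of two dialects: `samples-in-rows` (one row per sample, features in columns,
#' one column holding the class label) or `genes-in-rows` (one row per feature,
#' a header of sample identifiers, and one row holding the labels).
#'
#' @param path path to the delimited file.
#' @param label_column name of the label column (samples-in-rows) or label row
#'   identifier in the first column (genes-in-rows).
#' @param orientation `"samples-in-rows"` (default) or `"genes-in-rows"`.
#' @return a [labeled_dataset()].
#' @export
load_expression_table <- function(path, label_column = "label",
                                  orientation = c("samples-in-rows", "genes-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (orientation == "genes-in-rows") {
    if (!label_column %in% rownames(df)) {
      stop("label row '", label_column, "' not found in first column of ", path)
    }
    labels <- unlist(df[label_column, ], use.names = FALSE)
    df <- df[setdiff(rownames(df), label_column), , drop = FALSE]
    m <- t(as.matrix(df))
    suppressWarnings(mode(m) <- "numeric")
    if (anyNA(m)) stop("non-numeric or missing cell in expression block of ", path)
    labeled_dataset(m, labels, sample_ids = colnames(df), feature_ids = rownames(df))
  } else {
    if (!label_column %in% colnames(df)) {
      stop("label column '", label_column, "' not found in ", path)
    }
    labels <- df[[label_column]]
    df <- df[, setdiff(colnames(df), label_column), drop = FALSE]
    m <- as.matrix(df)
    suppressWarnings(mode(m) <- "numeric")
    if (anyNA(m)) stop("non-numeric or missing cell in expression block of ", path)
    labeled_dataset(m, labels, sample_ids = rownames(df), feature_ids = colnames(df))
  }
}

#' Write a labeled dataset to delimited text
#'
#' Inverse of [load_expression_table()] for the samples-in-rows dialect; the
#' original (decoded) labels are written to `label_column`. The class-code
#' mapping is additionally written as a small JSON sidecar (`<path>.labels.json`)
#' so that prediction-time decoding does not depend on re-reading the data.
#'
#' @param data a `labeled_dataset`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @param label_column name for the label column.
#' @param sidecar write the JSON label-map sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path, label_column = "label", sidecar = TRUE) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(data$matrix, check.names = FALSE)
  df[[label_column]] <- data$label_map[data$labels]
  utils::write.table(cbind(id = data$sample_ids, df), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(label_map = data$label_map, label_column = label_column),
                         paste0(path, ".labels.json"), auto_unbox = FALSE)
  }
  invisible(path)
}

subset_dataset <- function(data, idx) {
  # row subset keeping the global label coding (a class may drop below 2 here;
  # folds and subsamples legitimately do that, so bypass the constructor checks)
  structure(
    list(matrix = data$matrix[idx, , drop = FALSE], labels = data$labels[idx],
         sample_ids = data$sample_ids[idx], feature_ids = data$feature_ids,
         label_map = data$label_map),
    class = "labeled_dataset"
  )
}

#' Fit a feature standardizer on training data
#'
#' Computes per-feature mean and population standard deviation (divisor `n`)
#' on the training matrix. Standard deviations are floored at `1e-12`;
#' constant features therefore map to exactly 0 after transformation rather
#' than dividing by zero.
#'
#' @param train a `labeled_dataset` or numeric matrix (samples x features).
#' @return object of class `gpes_standardizer` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(train) {
  x <- if (inherits(train, "labeled_dataset")) train$matrix else as.matrix(train)
  if (nrow(x) < 1) stop("cannot fit a standardizer on an empty training set")
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  sdev <- sqrt(pmax(v, 0))
  sdev[sdev < 1e-12] <- 1e-12
  structure(list(mean = mu, sd = sdev), class = "gpes_standardizer")
}

#' Apply a fitted standardizer
#'
#' Transforms each feature as `(x - mean) / sd` with the statistics fitted by
#' [fit_standardizer()] — typically fitted on the training partition and
#' applied unchanged to validation and test data.
#'
#' @param s a `gpes_standardizer`.
#' @param data a `labeled_dataset` or numeric matrix with the same feature
#'   count as the fitting set.
#' @return same type as `data`, with the transformed matrix; labels and
#'   identifiers are untouched.
#' @export
apply_standardizer <- function(s, data) {
  x <- if (inherits(data, "labeled_dataset")) data$matrix else as.matrix(data)
  if (ncol(x) != length(s$mean)) {
    stop("feature count mismatch: standardizer fitted on ", length(s$mean),
         " features, data has ", ncol(x))
  }
  z <- sweep(sweep(x, 2, s$mean, "-"), 2, s$sd, "/")
  if (inherits(data, "labeled_dataset")) {
    data$matrix <- z
    data
  } else {
    z
  }
}
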