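default_tree_control <- function() {
  # fully grown CART: split whenever possible, no complexity pruning
  rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                       maxcompete = 0, maxsurrogate = 0, xval = 0)
}

#' Draw a random-subspace feature subset from the pool
#'
#' The subset size is one Gaussian(`nf_mean`, `nf_sd`) variate, rounded to the
#' nearest integer (half away from zero) and clipped to `[1, pool size]`; the
#' indices are then sampled uniformly without replacement from the pool. With
#' the defaults (mean 5, sd 3) each base tree sees about five features, so the
#' individual trees stay small and mutually diverse.
#'
#' @param pool a `feature_pool` or a plain integer vector of feature indices.
#' @param nf_mean,nf_sd Gaussian parameters for the subset size.
#' @return integer vector of global feature indices (subset of the pool).
#' @export
draw_feature_subset <- function(pool, nf_mean = 5, nf_sd = 3) {
  idx <- if (inherits(pool, "feature_pool")) pool$indices else as.integer(pool)
  if (!length(idx)) stop("empty feature pool")
  z <- stats::rnorm(1, nf_mean, nf_sd)
  size <- sign(z) * floor(abs(z) + 0.5)   # round half away from zero
  size <- min(max(size, 1L), length(idx))
  if (length(idx) == 1L) return(idx)
  sample(idx, size)
}

fit_tree <- function(X, y01) {
  # y01: factor with levels c("-1", "1")
  df <- data.frame(X, check.names = FALSE)
  colnames(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- y01
  rpart::rpart(.y ~ ., data = df, method = "class", control = default_tree_control())
}

predict_tree <- function(tree, X, features) {
  df <- data.frame(X[, features, drop = FALSE], check.names = FALSE)
  colnames(df) <- paste0("f", seq_along(features))
  as.integer(as.character(predict(tree, df, type = "class")))
}

#' Train one candidate decision tree
#'
#' Draws a fresh random feature subset from the pool and a fresh balanced
#' subsample of the training rows, fits a fully grown CART tree on that
#' restriction, and caches its hard votes and accuracy on the validation
#' partition.
#'
#' @param X standardized matrix of the full training partition.
#' @param y internal `-1/+1` labels for `X`'s rows.
#' @param pool a `feature_pool` (or index vector).
#' @param Xval,yval validation partition used for the cached votes/accuracy.
#' @param nf_mean,nf_sd subset-size Gaussian parameters.
#' @return object of class `base_classifier`: `tree`, `features` (global
#'   column indices), `subsample` (training rows used), `votes` (`-1/+1` per
#'   validation sample), `accuracy`.
#' @export
train_candidate_tree <- function(X, y, pool, Xval, yval, nf_mean = 5, nf_sd = 3) {
  features <- draw_feature_subset(pool, nf_mean, nf_sd)
  rows <- balanced_subsample(y)
  yf <- factor(y[rows], levels = c(-1, 1))
  tree <- fit_tree(X[rows, features, drop = FALSE], yf)
  votes <- predict_tree(tree, Xval, features)
  structure(
    list(tree = tree, features = features, subsample = rows,
         votes = votes, accuracy = mean(votes == yval)),
    class = "base_classifier"
  )
}

#' Generate the candidate set of base classifiers
#'
#' Trains `n` candidate trees (default 300), each with its own balanced
#' subsample and feature subset. Each candidate is trained under its own seed
#' drawn from the current random stream, so a fixed master seed reproduces the
#' whole set.
#'
#' @inheritParams train_candidate_tree
#' @param n number of candidates.
#' @return list of `base_classifier` records.
#' @export
generate_candidates <- function(X, y, pool, Xval, yval, n = 300,
                                nf_mean = 5, nf_sd = 3) {
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seeds, function(s) {
    set.seed(s)
    train_candidate_tree(X, y, pool, Xval, yval, nf_mean, nf_sd)
  })
}

#' Keep the above-average candidates
#'
#' Retains the records whose validation accuracy strictly exceeds the mean
#' accuracy of all records. If every record has the same accuracy (so the
#' strict rule would keep none), all are kept.
#'
#' @param records list of `base_classifier` records (or any list whose
#'   elements carry `$accuracy`).
#' @return the surviving sub-list.
#' @export
filter_above_average <- function(records) {
  if (!length(records)) stop("no records to filter")
  acc <- vapply(records, `[[`, numeric(1), "accuracy")
  keep <- acc > mean(acc)
  if (!any(keep)) records else records[keep]
}
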