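#' Rank features with a single selector
#'
#' Ranks the columns of a standardized training matrix for a binary problem
#' and returns the top `k` column indices, best first. Four selectors are
#' available:
#'
#' * `f_test` — one-way ANOVA F statistic per feature (closed form).
#' * `relief` — kernelised Relief: per sample, hit/miss neighbours contribute
#'   with weight `exp(-d / sigma)` (Euclidean distance, `sigma = 2` by
#'   default); a feature's weight is its summed miss-minus-hit absolute
#'   difference.
#' * `random_forest` — Gini importance summed over the trees of a small
#'   random forest (`rf_n_trees` trees).
#' * `svm_rfe` — recursive feature elimination with a linear soft-margin SVM
#'   (`cost = svm_cost`), dropping the `rfe_step` features with the smallest
#'   squared weights each iteration until `k` remain; the survivors are ranked
#'   by the final model's squared weights.
#'
#' Ties are broken by ascending column index (stable ranking).
#'
#' @param method one of `"f_test"`, `"relief"`, `"random_forest"`, `"svm_rfe"`.
#' @param X numeric matrix, samples x features.
#' @param y labels in `{-1, +1}` (any two-valued vector is accepted).
#' @param k number of features to return (`k <= ncol(X)`).
#' @param relief_sigma kernel width for `relief`.
#' @param rfe_step features removed per RFE iteration.
#' @param rf_n_trees trees for `random_forest` importance.
#' @param svm_cost soft-margin cost for `svm_rfe`.
#' @return integer vector of `k` column indices, ranked best-first. For
#'   `svm_rfe` the attribute `"n_iterations"` records how many elimination
#'   rounds were run.
#' @export
run_selector <- function(method = c("f_test", "relief", "random_forest", "svm_rfe"),
                         X, y, k,
                         relief_sigma = 2, rfe_step = 2, rf_n_trees = 10,
                         svm_cost = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (k > ncol(X)) stop("k (", k, ") exceeds the feature count (", ncol(X), ")")
  if (length(unique(y)) < 2) stop("degenerate labels: only one class present")
  switch(method,
    f_test = top_k(f_statistic(X, y), k),
    relief = top_k(relief_weights(X, y, sigma = relief_sigma), k),
    random_forest = top_k(rf_importance(X, y, n_trees = rf_n_trees), k),
    svm_rfe = svm_rfe_rank(X, y, k, step = rfe_step, cost = svm_cost)
  )
}

top_k <- function(score, k) {
  # stable: score descending, index ascending on ties
  order(-score, seq_along(score))[seq_len(k)]
}

f_statistic <- function(X, y) {
  g <- as.integer(factor(y))
  n <- nrow(X)
  ng <- tabulate(g)
  kg <- length(ng)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (j in seq_len(kg)) {
    Xi <- X[g == j, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + ng[j] * (mi - gm)^2
    ssw <- ssw + colSums(sweep(Xi, 2, mi, "-")^2)
  }
  msb <- ssb / (kg - 1)
  msw <- ssw / (n - kg)
  f <- msb / msw
  f[msw == 0 & msb == 0] <- 0       # constant feature: no signal
  f[msw == 0 & msb > 0] <- Inf      # perfectly separated constant-within-class
  f
}

relief_weights <- function(X, y, sigma = 2) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))      # Euclidean distances
  w <- numeric(ncol(X))
  for (i in seq_len(n)) {
    hit <- which(y == y[i]); hit <- hit[hit != i]
    miss <- which(y != y[i])
    if (!length(hit) || !length(miss)) next
    ph <- exp(-d2[i, hit] / sigma); ph <- ph / sum(ph)
    pm <- exp(-d2[i, miss] / sigma); pm <- pm / sum(pm)
    dh <- abs(sweep(X[hit, , drop = FALSE], 2, X[i, ], "-"))
    dm <- abs(sweep(X[miss, , drop = FALSE], 2, X[i, ], "-"))
    w <- w + colSums(dm * pm) - colSums(dh * ph)
  }
  w
}

rf_importance <- function(X, y, n_trees = 10) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- randomForest::randomForest(X, factor(y), ntree = n_trees,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp[match(colnames(X), rownames(fit$importance))]
}

svm_rfe_rank <- function(X, y, k, step = 2, cost = 1) {
  yf <- factor(y)
  remaining <- seq_len(ncol(X))
  iterations <- 0L
  w2 <- svm_weights2(X[, remaining, drop = FALSE], yf, cost)
  while (length(remaining) > k) {
    iterations <- iterations + 1L
    drop_n <- min(step, length(remaining) - k)
    # drop the drop_n smallest |w|^2; ties resolved toward larger index
    ord <- order(w2, -seq_along(w2))
    remaining <- remaining[-ord[seq_len(drop_n)]]
    w2 <- svm_weights2(X[, remaining, drop = FALSE], yf, cost)
  }
  ranked <- remaining[top_k(w2, length(remaining))]
  structure(ranked, n_iterations = iterations)
}

svm_weights2 <- function(X, yf, cost) {
  colnames(X) <- NULL
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(fit$SV, fit$coefs)  # primal weight vector
  as.numeric(w)^2
}

#' Build the deduplicated candidate feature pool
#'
#' Runs the four selectors (`f_test`, `relief`, `random_forest`, `svm_rfe`),
#' each returning its top `k_per_method` features, and keeps the union in
#' first-seen order (F-test list first, then the novel entries of each
#' subsequent list). With four 50-feature lists the pool size falls in
#' `[50, 200]`.
#'
#' @param X standardized training matrix (samples x features).
#' @param y binary labels.
#' @param k_per_method features requested from each selector (default 50;
#'   capped at `ncol(X)`).
#' @param selectors which selectors to run (default all four).
#' @inheritParams run_selector
#' @return object of class `feature_pool`: `indices` (unique, first-seen
#'   order), `per_method` (named list of ranked lists), `provenance` (named
#'   list: which methods picked each pooled index).
#' @export
build_feature_pool <- function(X, y, k_per_method = 50,
                               selectors = c("f_test", "relief", "random_forest", "svm_rfe"),
                               relief_sigma = 2, rfe_step = 2, rf_n_trees = 10,
                               svm_cost = 1) {
  k <- min(k_per_method, ncol(X))
  per_method <- lapply(selectors, function(m) {
    run_selector(m, X, y, k, relief_sigma = relief_sigma, rfe_step = rfe_step,
                 rf_n_trees = rf_n_trees, svm_cost = svm_cost)
  })
  names(per_method) <- selectors
  pool_from_lists(per_method)
}

#' Combine per-selector ranked lists into a deduplicated pool
#'
#' The union step of [build_feature_pool()]: concatenates the ranked lists in
#' order, drops duplicates keeping first occurrences, and records which
#' methods chose each surviving index. With `m` lists of `k` unique indices
#' each the pool size lies in `[k, m * k]` — `k` when all lists coincide,
#' `m * k` when they are pairwise disjoint.
#'
#' @param per_method named list of integer index vectors (ranked best-first).
#' @return a `feature_pool`.
#' @export
pool_from_lists <- function(per_method) {
  all_idx <- unlist(lapply(per_method, as.integer), use.names = FALSE)
  indices <- unique(all_idx)
  provenance <- lapply(indices, function(i) {
    names(per_method)[vapply(per_method, function(v) i %in% v, logical(1))]
  })
  names(provenance) <- as.character(indices)
  structure(list(indices = indices, per_method = per_method, provenance = provenance),
            class = "feature_pool")
}

#' @export
print.feature_pool <- function(x, ...) {
  cat("feature_pool:", length(x$indices), "unique features from",
      length(x$per_method), "selectors (",
      paste(names(x$per_method), collapse = ", "), ")\n")
  invisible(x)
}

#' Serialize a feature pool to JSON
#' @param pool a `feature_pool`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_pool <- function(pool, path) {
  jsonlite::write_json(
    list(indices = pool$indices,
         per_method = lapply(pool$per_method, as.integer),
         provenance = pool$provenance),
    path, auto_unbox = FALSE)
  invisible(path)
}
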