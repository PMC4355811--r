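#' Balanced subsample of a binary training set
#'
#' Draws `Ns = min(N1, N2)` samples per class without replacement, so the
#' minority class is retained in full and the majority class is thinned to
#' match it. Uses the current R random stream.
#'
#' @param y binary label vector (any two-valued coding).
#' @return integer vector of `2 * Ns` row indices (minority indices first,
#'   in original order; majority draw unordered).
#' @export
balanced_subsample <- function(y) {
  classes <- unique(y)
  if (length(classes) < 2) stop("balanced subsampling needs two classes")
  if (length(classes) > 2) stop("balanced_subsample is defined for binary labels")
  i1 <- which(y == classes[1])
  i2 <- which(y == classes[2])
  ns <- min(length(i1), length(i2))
  take <- function(idx) if (length(idx) == ns) idx else sort(sample(idx, ns))
  c(take(i1), take(i2))
}

#' Stratified k-fold assignment
#'
#' Randomly partitions samples into `k` folds so that within every class the
#' fold sizes differ by at most one, preserving the class ratio of the full
#' set up to integer rounding.
#'
#' @param y label vector; every class must have at least `k` samples.
#' @param k number of folds (default 3).
#' @return object of class `fold_assignment`: integer vector `fold` in
#'   `1..k` per sample, and `k`.
#' @export
stratified_kfold <- function(y, k = 3) {
  classes <- unique(y)
  cnt <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(cnt < k)) {
    stop("class smaller than k: ", paste(classes[cnt < k], collapse = ", "))
  }
  fold <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    idx <- sample(idx)                       # shuffle within class
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  structure(list(fold = fold, k = k), class = "fold_assignment")
}

#' Map folds to the five training phases
#'
#' The five training phases use two train/validation splits of the training
#' set: candidate trees are built on `train1` and filtered/evolved against
#' `val1` (Phases 1-3); the final generation is re-scored and the committee
#' searched on `train2`/`val2` (Phases 4-5). With folds A, B, C the default
#' mapping is `train1 = A + B`, `val1 = C`, `train2 = A + C`, `val2 = B`, so the
#' two validation sets are disjoint and each phase's train and validation sets
#' are disjoint.
#'
#' @param f a `fold_assignment` with `k = 3`.
#' @param val1_fold,val2_fold which folds serve as the two validation sets
#'   (distinct; defaults 3 and 2).
#' @return list with integer index vectors `train1`, `val1`, `train2`, `val2`.
#' @export
assign_phase_folds <- function(f, val1_fold = 3, val2_fold = 2) {
  stopifnot(inherits(f, "fold_assignment"))
  if (val1_fold == val2_fold) stop("the two validation folds must differ")
  idx <- seq_along(f$fold)
  list(
    train1 = idx[f$fold != val1_fold],
    val1   = idx[f$fold == val1_fold],
    train2 = idx[f$fold != val2_fold],
    val2   = idx[f$fold == val2_fold]
  )
}
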