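#' Confusion counts for binary or multiclass predictions
#'
#' For binary problems (`n_classes = 2`) returns TP/TN/FP/FN with class 1
#' treated as the positive class. For `c >= 2` classes also returns the
#' per-class one-vs-rest counts `tp`, `tn`, `fp`, `fn` (each length `c`).
#'
#' @param truth,pred integer class labels in `1..c`.
#' @param n_classes number of classes (default: max observed label).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth, pred, n_classes = max(truth, pred)) {
  stopifnot(length(truth) == length(pred))
  c_ <- n_classes
  tp <- fp <- fn <- tn <- integer(c_)
  for (i in seq_len(c_)) {
    tp[i] <- sum(truth == i & pred == i)
    fp[i] <- sum(truth != i & pred == i)
    fn[i] <- sum(truth == i & pred != i)
    tn[i] <- sum(truth != i & pred != i)
  }
  out <- list(n_classes = c_, n = length(truth), tp = tp, tn = tn, fp = fp, fn = fn)
  if (c_ == 2) {
    out$TP <- tp[1]; out$FN <- fn[1]; out$TN <- tp[2]; out$FP <- fp[1]
  }
  structure(out, class = "confusion_counts")
}

#' Two-point AUC for hard binary predictions
#'
#' `AUC = (sensitivity + specificity) / 2 = (TP/(TP+FN) + TN/(TN+FP)) / 2` —
#' the area under the one-threshold ROC polygon of a hard classifier,
#' identical to balanced accuracy.
#'
#' @param cc a binary `confusion_counts`, or `TP` given all four counts.
#' @param FN,TN,FP counts when calling with scalars.
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(cc, FN = NULL, TN = NULL, FP = NULL) {
  if (inherits(cc, "confusion_counts")) {
    if (cc$n_classes != 2) stop("auc_binary needs binary counts")
    TP <- cc$TP; FN <- cc$FN; TN <- cc$TN; FP <- cc$FP
  } else {
    TP <- cc
  }
  if (TP + FN == 0 || TN + FP == 0) stop("empty class: AUC undefined")
  (TP / (TP + FN) + TN / (TN + FP)) / 2
}

#' Micro-averaged precision, recall and F-score
#'
#' Pools the per-class counts before forming the ratios:
#' `P = sum(tp) / sum(tp + fp)`, `R = sum(tp) / sum(tp + fn)`,
#' `F = (beta^2 + 1) P R / (beta^2 P + R)`. For single-label classification
#' the pooled false positives and false negatives both equal the number of
#' errors, so micro precision, micro recall and the F-score all reduce to
#' plain accuracy.
#'
#' @param cc a `confusion_counts`.
#' @param beta recall weight (default 1).
#' @return named numeric vector `precision`, `recall`, `fscore`.
#' @export
micro_fscore <- function(cc, beta = 1) {
  denom_p <- sum(cc$tp + cc$fp)
  denom_r <- sum(cc$tp + cc$fn)
  if (denom_p == 0 || denom_r == 0) stop("zero denominator: micro scores undefined")
  p <- sum(cc$tp) / denom_p
  r <- sum(cc$tp) / denom_r
  if (beta^2 * p + r == 0) stop("zero denominator in F-score")
  c(precision = p, recall = r, fscore = (beta^2 + 1) * p * r / (beta^2 * p + r))
}

#' Average per-class accuracy
#'
#' Mean over classes of the one-vs-rest binary accuracy
#' `(tp_i + tn_i) / n`. Unlike plain accuracy it penalises a classifier that
#' sacrifices a hard class: every class contributes equally.
#'
#' @param cc a `confusion_counts` with `n_classes >= 2`.
#' @return accuracy-like score in `[0, 1]`.
#' @export
average_accuracy <- function(cc) {
  if (cc$n_classes < 2) stop("average accuracy needs at least two classes")
  mean((cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn))
}

#' Evaluate predictions against truth
#'
#' Convenience wrapper computing the report the package's experiments use:
#' accuracy always; AUC for binary problems; micro precision/recall/F-score
#' and average per-class accuracy for multiclass problems.
#'
#' @param truth,pred integer class labels in `1..c`.
#' @param n_classes number of classes.
#' @param beta F-score recall weight.
#' @return named list of metrics.
#' @export
evaluate_predictions <- function(truth, pred, n_classes = max(truth, pred), beta = 1) {
  cc <- confusion_counts(truth, pred, n_classes)
  out <- list(accuracy = mean(truth == pred))
  if (cc$n_classes == 2) {
    out$auc <- auc_binary(cc)
  }
  if (cc$n_classes >= 2) {
    mf <- micro_fscore(cc, beta)
    out$precision_micro <- unname(mf["precision"])
    out$recall_micro <- unname(mf["recall"])
    out$fscore_micro <- unname(mf["fscore"])
    out$average_accuracy <- average_accuracy(cc)
  }
  out
}
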