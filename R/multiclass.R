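#' Decompose a multiclass problem into binary subproblems
#'
#' One-vs-one (OVO) forms `c(c-1)/2` subproblems, each restricted to the
#' samples of its two classes (the lower class id is the positive, `+1`,
#' class). One-vs-rest (OVR) forms `c` subproblems over all samples, with the
#' named class positive and the rest negative. Balanced subsampling is applied
#' downstream inside each subproblem exactly as in the binary path.
#'
#' @param y integer class labels `1..c` with `c >= 3`.
#' @param scheme `"ovo"` or `"ovr"`.
#' @return list of subproblems, each a list with `scheme`, `positive`,
#'   `negative` (class id, or `NA` for "rest"), `rows` (sample indices used),
#'   `y` (`-1/+1` labels for those rows).
#' @export
decompose_multiclass <- function(y, scheme = c("ovo", "ovr")) {
  scheme <- match.arg(scheme)
  c_ <- max(y)
  if (c_ < 3) stop("decomposition needs at least 3 classes; use the binary path")
  if (scheme == "ovo") {
    pairs <- utils::combn(c_, 2)
    lapply(seq_len(ncol(pairs)), function(j) {
      pos <- pairs[1, j]; neg <- pairs[2, j]
      rows <- which(y %in% c(pos, neg))
      list(scheme = "ovo", positive = pos, negative = neg, rows = rows,
           y = ifelse(y[rows] == pos, 1, -1))
    })
  } else {
    lapply(seq_len(c_), function(pos) {
      list(scheme = "ovr", positive = pos, negative = NA_integer_,
           rows = seq_along(y), y = ifelse(y == pos, 1, -1))
    })
  }
}

#' Decode binary subproblem outputs into class labels
#'
#' OVO: each subproblem votes for its positive or negative class; the
#' predicted class is the vote argmax, ties broken toward the smallest class
#' id. OVR: the predicted class is the unique class voting `+1`; when several
#' (or none) do, the class with the largest committee vote margin among the
#' `+1` voters (or among all classes if none voted `+1`) wins, ties again to
#' the smallest id.
#'
#' @param subproblems the list returned by [decompose_multiclass()] (the
#'   `rows`/`y` fields are not consulted, only the scheme and class ids).
#' @param predictions matrix (samples x subproblems) of `-1/+1` outputs.
#' @param margins matrix of signed committee vote sums, same shape as
#'   `predictions`; required for OVR tie resolution (defaults to
#'   `predictions` itself, i.e. margins of a size-1 committee).
#' @param n_classes class count `c`.
#' @return integer class labels in `1..c`.
#' @export
decode_votes <- function(subproblems, predictions, margins = NULL,
                         n_classes = NULL) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) != length(subproblems)) {
    stop("one prediction column per subproblem is required")
  }
  if (is.null(margins)) margins <- predictions
  scheme <- subproblems[[1]]$scheme
  if (is.null(n_classes)) {
    n_classes <- max(vapply(subproblems, function(s) {
      max(s$positive, s$negative, na.rm = TRUE)
    }, numeric(1)))
  }
  n <- nrow(predictions)
  out <- integer(n)
  if (scheme == "ovo") {
    for (s in seq_len(n)) {
      tally <- numeric(n_classes)
      for (j in seq_along(subproblems)) {
        cl <- if (predictions[s, j] > 0) subproblems[[j]]$positive else subproblems[[j]]$negative
        tally[cl] <- tally[cl] + 1
      }
      out[s] <- which.max(tally)     # ties: smallest class id
    }
  } else {
    for (s in seq_len(n)) {
      pos <- which(predictions[s, ] > 0)
      cand <- if (length(pos)) pos else seq_along(subproblems)
      best <- cand[which.max(margins[s, cand])]
      out[s] <- subproblems[[best]]$positive
    }
  }
  out
}
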