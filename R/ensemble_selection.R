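#' Majority vote of committee members
#'
#' Per sample, the sign of the summed member votes. The member count must be
#' odd so the sum is never zero.
#'
#' @param member_votes numeric matrix (samples x members) of `-1/+1` votes.
#' @return `-1/+1` vector, one entry per sample.
#' @export
majority_vote <- function(member_votes) {
  member_votes <- as.matrix(member_votes)
  if (ncol(member_votes) %% 2 == 0) {
    stop("majority voting requires an odd number of members, got ", ncol(member_votes))
  }
  ifelse(rowSums(member_votes) < 0, -1, 1)
}

#' Majority-voting error (MVE)
#'
#' Fraction of validation samples misclassified by the committee's majority
#' vote.
#'
#' @param member_votes numeric matrix (validation samples x members).
#' @param y `-1/+1` truth for the validation samples.
#' @return error in `[0, 1]`.
#' @export
mve <- function(member_votes, y) {
  if (!length(y)) stop("empty validation set")
  mean(majority_vote(member_votes) != y)
}

#' Keep the above-average individuals of a population
#'
#' Same strict above-the-mean rule (with all-equal fallback) as for candidate
#' trees, applied to the re-scored accuracies of the final GP generation.
#'
#' @param population list of `gp_individual`s with `fitness` set to the
#'   phase-4 validation accuracy.
#' @return the surviving sub-list.
#' @export
filter_above_average_individuals <- function(population) {
  if (!length(population)) stop("empty population")
  acc <- vapply(population, `[[`, numeric(1), "fitness")
  keep <- acc > mean(acc)
  if (!any(keep)) population else population[keep]
}

#' Forward search for the final committee
#'
#' Starts from the single best candidate and greedily grows the committee by
#' pairs: at every step the pair of remaining candidates whose addition gives
#' the lowest majority-voting error is added. A step with unchanged (or tied)
#' MVE is still taken — only a strictly worse MVE stops the search, which
#' deliberately lets the committee keep absorbing members to reduce variance —
#' or the search stops when fewer than two candidates remain. Among tied
#' pairs, the pair with the larger summed individual accuracy wins, then the
#' lexicographically first pair.
#'
#' @param candidate_votes matrix (validation samples x candidates) of `-1/+1`
#'   votes.
#' @param y `-1/+1` truth for the validation samples.
#' @param accuracies per-candidate individual accuracy (defaults to agreement
#'   of each vote column with `y`); used to pick the starting member and to
#'   break ties.
#' @return object of class `ensemble_committee`: `members` (column indices
#'   into `candidate_votes`, in selection order), `trace` (MVE after the
#'   initial member and after each accepted pair), `rejected_mve` (the
#'   strictly-worse MVE that ended the search, or `NA` on exhaustion).
#' @export
forward_search <- function(candidate_votes, y, accuracies = NULL) {
  candidate_votes <- as.matrix(candidate_votes)
  L <- ncol(candidate_votes)
  if (!L) stop("no candidates for the forward search")
  if (is.null(accuracies)) {
    accuracies <- colMeans(candidate_votes == y)
  }
  members <- which.max(accuracies)   # ties: lowest index
  remaining <- setdiff(seq_len(L), members)
  current <- mve(candidate_votes[, members, drop = FALSE], y)
  trace <- current
  rejected <- NA_real_
  while (length(remaining) >= 2) {
    pairs <- utils::combn(remaining, 2)
    pair_mve <- apply(pairs, 2, function(p) {
      mve(candidate_votes[, c(members, p), drop = FALSE], y)
    })
    pair_acc <- accuracies[pairs[1, ]] + accuracies[pairs[2, ]]
    best <- order(pair_mve, -pair_acc, pairs[1, ], pairs[2, ])[1]
    if (pair_mve[best] > current) {
      rejected <- pair_mve[best]
      break
    }
    members <- c(members, pairs[, best])
    remaining <- setdiff(remaining, pairs[, best])
    current <- pair_mve[best]
    trace <- c(trace, current)
  }
  structure(list(members = members, trace = trace, rejected_mve = rejected),
            class = "ensemble_committee")
}

#' @export
print.ensemble_committee <- function(x, ...) {
  cat("ensemble_committee:", length(x$members), "members; MVE trace:",
      paste(signif(x$trace, 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Predict with a committee of GP individuals
#'
#' Majority vote over the member individuals' predictions.
#'
#' @param committee list of `gp_individual`s (odd length).
#' @param votes pool vote matrix (samples x pool classifiers), or `NULL` to
#'   compute it from `X` and `pool`.
#' @inheritParams predict_individual
#' @return `-1/+1` predictions, one per sample.
#' @export
predict_committee <- function(committee, X = NULL, pool = NULL, votes = NULL) {
  if (is.null(votes)) votes <- pool_votes(pool, X)
  member_votes <- vapply(committee, function(ind) evaluate_node(ind$root, votes),
                         numeric(nrow(votes)))
  majority_vote(matrix(member_votes, nrow = nrow(votes)))
}

#' Operator frequencies over committee members
#'
#' Shares of `Min`, `Average` and `Max` among all fusion-operator nodes of
#' the committee members (summing to 1).
#'
#' @param committee list of `gp_individual`s.
#' @return named numeric vector with entries `Min`, `Average`, `Max`.
#' @export
operator_frequencies <- function(committee) {
  count_ops <- function(node) {
    if (node$kind == "terminal") return(c(Min = 0, Average = 0, Max = 0))
    out <- c(Min = 0, Average = 0, Max = 0)
    out[node$op] <- 1
    for (ch in node$children) out <- out + count_ops(ch)
    out
  }
  tot <- Reduce(`+`, lapply(committee, function(ind) count_ops(ind$root)))
  tot[c("Min", "Average", "Max")] / sum(tot)
}
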