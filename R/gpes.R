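#' Fit a genetic-programming ensemble of decision trees
#'
#' Trains the full five-phase ensemble on a samples x features expression
#' matrix. For a binary problem the training set is split into three
#' stratified folds giving two train/validation splits; then:
#'
#' 1. **Candidate generation** — `n_candidates` fully grown CART trees, each
#'    on a fresh balanced subsample of `train1` and a fresh Gaussian-sized
#'    random subset of the candidate feature pool (union of the top
#'    `k_per_method` features of four selectors).
#' 2. **Candidate filtering** — trees with strictly above-average accuracy on
#'    `val1` become the GP terminal set.
#' 3. **Evolution** — genetic programming evolves ternary Min/Max/Average
#'    fusion trees over the terminal set; fitness is accuracy on `val1`.
#' 4. **Individual filtering** — the final generation is re-scored on the
#'    second split (by default the terminal trees are refitted on `train2`)
#'    and the above-average individuals are kept.
#' 5. **Forward search** — the final committee is grown pairwise from the
#'    best individual, minimising majority-voting error on `val2`; only a
#'    strictly worse error stops the search.
#'
#' Problems with three or more classes are decomposed into binary
#' subproblems (one-vs-one or one-vs-rest), each trained independently with
#' the same pipeline, and predictions are decoded by vote tally.
#'
#' @param x numeric matrix (samples x features) or `labeled_dataset`.
#' @param y class labels (ignored when `x` is a `labeled_dataset`).
#' @param scheme multiclass decomposition: `"auto"` (OVO when `c >= 3`),
#'   `"ovo"` or `"ovr"`.
#' @param n_candidates candidate trees generated in Phase 1.
#' @param k_per_method features requested from each of the four selectors.
#' @param selectors feature selectors to use (see [run_selector()]).
#' @param pop_size,generations,crossover_rate,mutation_rate GP parameters
#'   (see [gp_config()]).
#' @param nf_mean,nf_sd Gaussian parameters of the random-subspace size.
#' @param relief_sigma,rfe_step,rf_n_trees,svm_cost selector parameters.
#' @param fitness_cv `"holdout"` scores fitness on `val1`; `"10fold"`
#'   averages per-fold accuracy over a stratified 10-fold split of the pooled
#'   `train1 + val1` votes.
#' @param phase4 `"refit"` refits the terminal trees on `train2` before
#'   re-scoring on `val2`; `"rescore"` keeps the Phase-1 trees.
#' @param n_folds folds for the phase split (default 3).
#' @param seed integer seed; set for a fully reproducible fit.
#' @param verbose print per-phase progress.
#' @return an object of class `gpes`; see [predict.gpes()],
#'   [summary.gpes()], [plot.gpes()].
#' @examples
#' \donttest{
#' d <- make_dataset(synthetic_spec(n_per_class = c(20, 20), n_features = 300,
#'                                  n_informative = 10, shift = 2), seed = 1)
#' fit <- gpes(d, n_candidates = 60, pop_size = 20, generations = 10, seed = 1)
#' table(predict(fit, d$matrix), d$label_map[d$labels])
#' }
#' @export
gpes <- function(x, y = NULL,
                 scheme = c("auto", "ovo", "ovr"),
                 n_candidates = 300, k_per_method = 50,
                 selectors = c("f_test", "relief", "random_forest", "svm_rfe"),
                 pop_size = 80, generations = 200,
                 crossover_rate = 0.8, mutation_rate = 0.4,
                 nf_mean = 5, nf_sd = 3,
                 relief_sigma = 2, rfe_step = 2, rf_n_trees = 10, svm_cost = 1,
                 fitness_cv = c("holdout", "10fold"),
                 phase4 = c("refit", "rescore"),
                 n_folds = 3, seed = NULL, verbose = FALSE) {
  cl <- match.call()
  scheme <- match.arg(scheme)
  fitness_cv <- match.arg(fitness_cv)
  phase4 <- match.arg(phase4)
  data <- if (inherits(x, "labeled_dataset")) x else labeled_dataset(x, y)
  if (!is.null(seed)) set.seed(seed)

  cfg <- list(scheme = scheme, n_candidates = n_candidates,
              k_per_method = k_per_method, selectors = selectors,
              gp = gp_config(pop_size = pop_size, generations = generations,
                             crossover_rate = crossover_rate,
                             mutation_rate = mutation_rate),
              nf_mean = nf_mean, nf_sd = nf_sd,
              relief_sigma = relief_sigma, rfe_step = rfe_step,
              rf_n_trees = rf_n_trees, svm_cost = svm_cost,
              fitness_cv = fitness_cv, phase4 = phase4, n_folds = n_folds,
              seed = seed)

  std <- fit_standardizer(data)
  z <- apply_standardizer(std, data$matrix)
  c_ <- n_classes(data)

  if (c_ == 2) {
    ybin <- ifelse(data$labels == 1, 1, -1)   # class id 1 is the positive class
    fit <- fit_binary_gpes(z, ybin, cfg, verbose)
    subfits <- NULL
    subproblems <- NULL
  } else {
    use_scheme <- if (scheme == "auto") "ovo" else scheme
    cfg$scheme <- use_scheme
    subproblems <- decompose_multiclass(data$labels, use_scheme)
    subfits <- lapply(seq_along(subproblems), function(j) {
      if (verbose) message("subproblem ", j, "/", length(subproblems))
      sp <- subproblems[[j]]
      fit_binary_gpes(z[sp$rows, , drop = FALSE], sp$y, cfg, verbose)
    })
    fit <- NULL
  }

  structure(list(call = cl, config = cfg, label_map = data$label_map,
                 n_classes = c_, feature_ids = data$feature_ids,
                 standardizer = std, binary = fit,
                 subproblems = subproblems, subfits = subfits),
            class = "gpes")
}

# The five phases for one binary problem on an already-standardized matrix z
# with -1/+1 labels. Returns pool, committee, per-phase accuracies and traces.
fit_binary_gpes <- function(z, ybin, cfg, verbose = FALSE) {
  folds <- stratified_kfold(ybin, cfg$n_folds)
  ph <- assign_phase_folds(folds)
  X1 <- z[ph$train1, , drop = FALSE]; y1 <- ybin[ph$train1]
  Xv1 <- z[ph$val1, , drop = FALSE]; yv1 <- ybin[ph$val1]
  X2 <- z[ph$train2, , drop = FALSE]; y2 <- ybin[ph$train2]
  Xv2 <- z[ph$val2, , drop = FALSE]; yv2 <- ybin[ph$val2]

  if (verbose) message("feature pool ...")
  pool <- build_feature_pool(X1, y1, k_per_method = cfg$k_per_method,
                             selectors = cfg$selectors,
                             relief_sigma = cfg$relief_sigma,
                             rfe_step = cfg$rfe_step,
                             rf_n_trees = cfg$rf_n_trees,
                             svm_cost = cfg$svm_cost)

  if (verbose) message("phase 1: ", cfg$n_candidates, " candidate trees ...")
  candidates <- generate_candidates(X1, y1, pool, Xv1, yv1,
                                    n = cfg$n_candidates,
                                    nf_mean = cfg$nf_mean, nf_sd = cfg$nf_sd)
  acc1 <- vapply(candidates, `[[`, numeric(1), "accuracy")

  if (verbose) message("phase 2: filtering candidates ...")
  terminals <- filter_above_average(candidates)
  acc2 <- vapply(terminals, `[[`, numeric(1), "accuracy")

  if (verbose) message("phase 3: evolving ", cfg$gp$generations, " generations ...")
  if (cfg$fitness_cv == "10fold") {
    # pooled train1+val1 votes, fitness averaged over a stratified 10-fold split
    Xf <- rbind(X1, Xv1); yf <- c(y1, yv1)
    vf <- pool_votes(terminals, Xf)
    ff <- stratified_kfold(yf, 10)$fold
    evo <- gp_evolve(cfg$gp, vf, yf, fitness_fold = ff)
  } else {
    evo <- gp_evolve(cfg$gp, cached_pool_votes(terminals), yv1)
  }
  acc3 <- vapply(evo$population, `[[`, numeric(1), "fitness")

  if (verbose) message("phase 4: re-scoring the final generation ...")
  if (cfg$phase4 == "refit") {
    pool_p4 <- lapply(terminals, function(b) {
      rows <- balanced_subsample(y2)
      tree <- fit_tree(X2[rows, b$features, drop = FALSE],
                       factor(y2[rows], levels = c(-1, 1)))
      b$tree <- tree
      b$subsample <- rows
      b$votes <- predict_tree(tree, Xv2, b$features)
      b$accuracy <- mean(b$votes == yv2)
      b
    })
  } else {
    pool_p4 <- lapply(terminals, function(b) {
      b$votes <- predict_tree(b$tree, Xv2, b$features)
      b$accuracy <- mean(b$votes == yv2)
      b
    })
  }
  votes2 <- cached_pool_votes(pool_p4)
  pop2 <- lapply(evo$population, function(ind) {
    ind$fitness <- individual_accuracy(ind, votes2, yv2)
    ind
  })
  available <- filter_above_average_individuals(pop2)
  acc4 <- vapply(available, `[[`, numeric(1), "fitness")

  if (verbose) message("phase 5: forward search over ", length(available), " individuals ...")
  ind_votes <- vapply(available, function(ind) evaluate_node(ind$root, votes2),
                      numeric(nrow(votes2)))
  ind_votes <- matrix(ind_votes, nrow = nrow(votes2))
  search <- forward_search(ind_votes, yv2, accuracies = acc4)
  committee <- available[search$members]

  list(pool = pool, terminals = pool_p4, committee = committee,
       committee_search = search,
       phase_accuracy = c(phase1 = mean(acc1), phase2 = mean(acc2),
                          phase3 = mean(acc3), phase4 = mean(acc4),
                          phase5 = 1 - search$trace[length(search$trace)]),
       gp_history = evo$history,
       operator_freq = operator_frequencies(committee),
       folds = ph)
}

binary_predict_votes <- function(fit, z) {
  votes <- pool_votes(fit$terminals, z)
  member <- vapply(fit$committee, function(ind) evaluate_node(ind$root, votes),
                   numeric(nrow(z)))
  member <- matrix(member, nrow = nrow(z))
  list(pred = majority_vote(member), margin = rowSums(member))
}

align_features <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_ids %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_ids)) {
    stop("newdata has ", ncol(newdata), " features; the model was fitted on ",
         length(object$feature_ids),
         " (name the columns to allow reordering)")
  }
  newdata
}

#' Predict classes with a fitted GPES model
#'
#' Standardizes `newdata` with the training-set standardizer (columns are
#' aligned by name when present), applies every committee member and takes
#' the majority vote; multiclass subproblem outputs are decoded by vote
#' tally.
#'
#' @param object a fitted [gpes()] model.
#' @param newdata numeric matrix (samples x features) or `labeled_dataset`.
#' @param type `"class"` for decoded labels (original coding), `"code"` for
#'   integer class ids `1..c`.
#' @param ... unused.
#' @return vector of predicted labels.
#' @export
predict.gpes <- function(object, newdata, type = c("class", "code"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$matrix
  newdata <- align_features(object, newdata)
  z <- apply_standardizer(object$standardizer, newdata)
  if (object$n_classes == 2) {
    p <- binary_predict_votes(object$binary, z)$pred
    code <- ifelse(p > 0, 1L, 2L)
  } else {
    outs <- lapply(object$subfits, binary_predict_votes, z = z)
    pred <- vapply(outs, `[[`, numeric(nrow(z)), "pred")
    marg <- vapply(outs, `[[`, numeric(nrow(z)), "margin")
    code <- decode_votes(object$subproblems, matrix(pred, nrow = nrow(z)),
                         matrix(marg, nrow = nrow(z)),
                         n_classes = object$n_classes)
  }
  if (type == "code") code else object$label_map[code]
}

#' @export
print.gpes <- function(x, ...) {
  cat("GPES ensemble classifier\n")
  cat("  classes:", paste(x$label_map, collapse = ", "),
      if (x$n_classes > 2) paste0("(", toupper(x$config$scheme), " decomposition)"), "\n")
  if (x$n_classes == 2) {
    cat("  feature pool:", length(x$binary$pool$indices), "features;",
        length(x$binary$terminals), "terminal trees;",
        "committee of", length(x$binary$committee), "\n")
  } else {
    cat(" ", length(x$subfits), "binary subproblems; committee sizes:",
        paste(vapply(x$subfits, function(f) length(f$committee), integer(1)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise a fitted GPES model
#'
#' Reports per-phase mean validation accuracy, the committee's MVE trace and
#' the fusion-operator frequencies (per subproblem for multiclass fits).
#'
#' @param object a fitted [gpes()] model.
#' @param ... unused.
#' @return a `summary.gpes` list, printed as a small report.
#' @export
summary.gpes <- function(object, ...) {
  fits <- if (object$n_classes == 2) list(object$binary) else object$subfits
  out <- list(
    n_classes = object$n_classes,
    scheme = object$config$scheme,
    label_map = object$label_map,
    phase_accuracy = t(vapply(fits, `[[`, numeric(5), "phase_accuracy")),
    committee_sizes = vapply(fits, function(f) length(f$committee), integer(1)),
    pool_sizes = vapply(fits, function(f) length(f$pool$indices), integer(1)),
    mve_traces = lapply(fits, function(f) f$committee_search$trace),
    operator_freq = t(vapply(fits, `[[`, numeric(3), "operator_freq"))
  )
  class(out) <- "summary.gpes"
  out
}

#' @export
print.summary.gpes <- function(x, ...) {
  cat("GPES fit:", x$n_classes, "classes",
      if (x$n_classes > 2) paste0("(", toupper(x$scheme), ")"), "\n")
  cat("mean validation accuracy per phase:\n")
  print(round(colMeans(x$phase_accuracy), 4))
  cat("committee sizes:", paste(x$committee_sizes, collapse = ", "), "\n")
  cat("feature-pool sizes:", paste(x$pool_sizes, collapse = ", "), "\n")
  cat("operator frequencies (Min / Average / Max):",
      paste(round(colMeans(x$operator_freq), 3), collapse = " / "), "\n")
  invisible(x)
}

#' Plot per-phase validation accuracy of a GPES fit
#'
#' Line plot of the mean validation accuracy after each of the five training
#' phases (averaged over subproblems for multiclass fits), the qualitative
#' phase curve of the training procedure.
#'
#' @param x a fitted [gpes()] model.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gpes <- function(x, ...) {
  fits <- if (x$n_classes == 2) list(x$binary) else x$subfits
  pa <- colMeans(t(vapply(fits, `[[`, numeric(5), "phase_accuracy")))
  graphics::plot(1:5, pa, type = "b", pch = 19, xaxt = "n",
                 xlab = "training phase", ylab = "mean validation accuracy", ...)
  graphics::axis(1, at = 1:5, labels = paste("Phase", 1:5))
  invisible(x)
}
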