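GP_OPERATORS <- c("Average", "Min", "Max")

#' GP node constructors
#'
#' A GP individual is a ternary syntax tree over hard `-1/+1` votes. Terminal
#' nodes reference a base classifier by its position in the terminal pool;
#' nonterminal nodes carry one of the three fusion operators and exactly three
#' children:
#'
#' * `Min`  — outputs `-1` if any child outputs `-1` (vetoes toward negative);
#' * `Max`  — outputs `+1` if any child outputs `+1` (vetoes toward positive);
#' * `Average` — majority vote of its three children (`-1` iff the child mean
#'   is below 0; with three odd votes the mean is never 0).
#'
#' @param index terminal: position of the referenced classifier in the pool.
#' @param op nonterminal: `"Average"`, `"Min"` or `"Max"`.
#' @param children list of exactly three GP nodes.
#' @return a `gp_node` list.
#' @export
gp_terminal <- function(index) {
  structure(list(kind = "terminal", index = as.integer(index)), class = "gp_node")
}

#' @rdname gp_terminal
#' @export
gp_operator <- function(op, children) {
  op <- match.arg(op, GP_OPERATORS)
  if (length(children) != 3) stop("nonterminal nodes take exactly three children")
  structure(list(kind = "nonterminal", op = op, children = children), class = "gp_node")
}

#' Wrap a root node as a GP individual
#'
#' The root must be a nonterminal and the tree depth (root = depth 1) at
#' most `max_depth`.
#'
#' @param root a nonterminal `gp_node`.
#' @param max_depth depth cap (default 3).
#' @return a `gp_individual` with unset fitness.
#' @export
gp_individual <- function(root, max_depth = 3) {
  if (root$kind != "nonterminal") stop("the root of a GP individual must be a fusion operator")
  if (node_depth(root) > max_depth) stop("individual exceeds the depth limit of ", max_depth)
  structure(list(root = root, fitness = NA_real_), class = "gp_individual")
}

node_depth <- function(node) {
  if (node$kind == "terminal") return(1L)
  1L + max(vapply(node$children, node_depth, integer(1)))
}

terminal_indices <- function(node) {
  if (node$kind == "terminal") return(node$index)
  unlist(lapply(node$children, terminal_indices))
}

#' Evaluate a GP node on a vote matrix
#'
#' Applies the fusion-tree semantics sample-wise: `Min` is the minimum and
#' `Max` the maximum of the three child outputs in `{-1, +1}`, and `Average`
#' is their majority. `votes` holds the hard votes of every pool classifier.
#'
#' @param node a `gp_node`.
#' @param votes numeric matrix (samples x pool classifiers) of `-1/+1` votes;
#'   a plain vector is treated as the votes of one sample.
#' @return `-1/+1` vector with one entry per sample.
#' @export
evaluate_node <- function(node, votes) {
  if (is.vector(votes)) votes <- matrix(votes, nrow = 1)
  eval_node_m(node, votes)
}

eval_node_m <- function(node, V) {
  if (node$kind == "terminal") {
    if (node$index > ncol(V)) stop("unresolved classifier reference: ", node$index)
    return(V[, node$index])
  }
  c1 <- eval_node_m(node$children[[1]], V)
  c2 <- eval_node_m(node$children[[2]], V)
  c3 <- eval_node_m(node$children[[3]], V)
  switch(node$op,
    Min = pmin(c1, c2, c3),
    Max = pmax(c1, c2, c3),
    Average = ifelse(c1 + c2 + c3 < 0, -1, 1)
  )
}

#' Predict with a GP individual
#'
#' Either evaluates the individual on a precomputed pool vote matrix
#' (`votes`), or computes the needed base-classifier votes from a feature
#' matrix `X` and the terminal pool.
#'
#' @param ind a `gp_individual`.
#' @param X standardized feature matrix (ignored when `votes` is given).
#' @param pool list of `base_classifier` records backing the terminals.
#' @param votes optional precomputed vote matrix (samples x pool classifiers).
#' @return `-1/+1` predictions, one per sample.
#' @export
predict_individual <- function(ind, X = NULL, pool = NULL, votes = NULL) {
  if (is.null(votes)) {
    if (is.null(X) || is.null(pool)) stop("supply either `votes` or both `X` and `pool`")
    votes <- pool_votes(pool, X)
  }
  evaluate_node(ind$root, votes)
}

pool_votes <- function(pool, X) {
  v <- vapply(pool, function(b) predict_tree(b$tree, X, b$features), numeric(nrow(X)))
  matrix(v, nrow = nrow(X))
}

cached_pool_votes <- function(pool) {
  nval <- length(pool[[1]]$votes)
  matrix(vapply(pool, `[[`, numeric(nval), "votes"), nrow = nval)
}

#' GP configuration
#'
#' Collects the evolutionary-search parameters. The defaults are the
#' operating point used throughout the package: population 80, 200
#' generations, crossover rate 0.8, mutation rate 0.4 (per individual, one
#' node changed), ramped half-and-half initialisation over depths 2..3,
#' binary tournament selection with elitism of one.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations.
#' @param crossover_rate,mutation_rate probabilities in `[0, 1]`.
#' @param init_depths target depths for ramped half-and-half initialisation.
#' @param max_depth individual depth cap (root = depth 1).
#' @param tournament_size selection tournament size.
#' @param elitism number of best individuals copied unchanged per generation.
#' @return a `gp_config` list.
#' @export
gp_config <- function(pop_size = 80, generations = 200, crossover_rate = 0.8,
                      mutation_rate = 0.4, init_depths = 2:3, max_depth = 3,
                      tournament_size = 2, elitism = 1) {
  stopifnot(pop_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            all(init_depths >= 2), all(init_depths <= max_depth))
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 init_depths = init_depths, max_depth = max_depth,
                 tournament_size = tournament_size, elitism = elitism),
            class = "gp_config")
}

random_full_tree <- function(depth, pool_size) {
  # all nodes above the target depth are operators; leaves sit exactly at `depth`
  grow <- function(d) {
    if (d == depth) return(gp_terminal(sample.int(pool_size, 1)))
    gp_operator(sample(GP_OPERATORS, 1), lapply(1:3, function(i) grow(d + 1)))
  }
  grow(1)
}

random_grow_tree <- function(max_d, pool_size) {
  # root is an operator; below it, node kinds are drawn at random until max_d
  grow <- function(d, force_op = FALSE) {
    if (d == max_d || (!force_op && stats::runif(1) < 0.5)) {
      return(gp_terminal(sample.int(pool_size, 1)))
    }
    gp_operator(sample(GP_OPERATORS, 1), lapply(1:3, function(i) grow(d + 1)))
  }
  grow(1, force_op = TRUE)
}

#' Ramped half-and-half initial population
#'
#' Splits the population evenly across the target depths; within each depth,
#' half of the trees are "full" (every level above the target depth is a
#' fusion operator, leaves exactly at the target depth) and half are "grow"
#' (below the root, node kinds are drawn at random, so trees are typically
#' unbalanced). Remainders after the even split go to the earliest
#' (depth, method) cells.
#'
#' @param cfg a [gp_config()].
#' @param pool_size number of available terminal classifiers.
#' @return list of `gp_individual`s of length `cfg$pop_size`.
#' @export
ramped_half_and_half_init <- function(cfg, pool_size) {
  if (pool_size < 1) stop("terminal pool is empty")
  cells <- expand.grid(depth = cfg$init_depths, method = c("full", "grow"),
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  base <- cfg$pop_size %/% n_cells
  extra <- cfg$pop_size %% n_cells
  counts <- rep(base, n_cells) + c(rep(1, extra), rep(0, n_cells - extra))
  pop <- vector("list", cfg$pop_size)
  k <- 0L
  for (i in seq_len(n_cells)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      root <- if (cells$method[i] == "full") {
        random_full_tree(cells$depth[i], pool_size)
      } else {
        random_grow_tree(cells$depth[i], pool_size)
      }
      pop[[k]] <- gp_individual(root, cfg$max_depth)
    }
  }
  pop
}

# Enumerate node paths; path = integer vector of child positions from the root
# (length 0 = the root itself).
node_paths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (node$kind == "nonterminal") {
    for (i in 1:3) {
      out <- c(out, node_paths(node$children[[i]], c(prefix, i)))
    }
  }
  out
}

get_subtree <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

set_subtree <- function(node, path, sub) {
  if (!length(path)) return(sub)
  node$children[[path[1]]] <- set_subtree(node$children[[path[1]]], path[-1], sub)
  node
}

#' Subtree crossover
#'
#' Picks one non-root subtree in each parent uniformly at random and swaps
#' them. If either offspring would exceed the depth cap, the crossover points
#' are re-drawn (up to `max_retries` times); if no legal pair is found the
#' parents are returned unchanged. Arity and root invariants always hold.
#'
#' @param a,b parent `gp_individual`s.
#' @param max_depth depth cap.
#' @param max_retries crossover-point re-draws before falling back to copies.
#' @return list of two offspring `gp_individual`s.
#' @export
gp_crossover <- function(a, b, max_depth = 3, max_retries = 10) {
  pa <- node_paths(a$root); pa <- pa[lengths(pa) > 0]
  pb <- node_paths(b$root); pb <- pb[lengths(pb) > 0]
  for (try in seq_len(max_retries)) {
    cut_a <- pa[[sample.int(length(pa), 1)]]
    cut_b <- pb[[sample.int(length(pb), 1)]]
    ra <- set_subtree(a$root, cut_a, get_subtree(b$root, cut_b))
    rb <- set_subtree(b$root, cut_b, get_subtree(a$root, cut_a))
    if (node_depth(ra) <= max_depth && node_depth(rb) <= max_depth) {
      return(list(gp_individual(ra, max_depth), gp_individual(rb, max_depth)))
    }
  }
  list(a, b)
}

#' Point mutation
#'
#' Replaces one uniformly chosen node: a terminal gets a fresh random pool
#' reference, a nonterminal (the root included) gets a different fusion
#' operator. The tree structure is unchanged.
#'
#' @param ind a `gp_individual`.
#' @param pool_size number of available terminal classifiers.
#' @param max_depth depth cap (carried through unchanged).
#' @return the mutated `gp_individual` (fitness reset).
#' @export
gp_mutate <- function(ind, pool_size, max_depth = 3) {
  paths <- node_paths(ind$root)
  path <- paths[[sample.int(length(paths), 1)]]
  node <- get_subtree(ind$root, path)
  if (node$kind == "terminal") {
    node$index <- sample.int(pool_size, 1)
  } else {
    node$op <- sample(setdiff(GP_OPERATORS, node$op), 1)
  }
  gp_individual(set_subtree(ind$root, path, node), max_depth)
}

individual_accuracy <- function(ind, votes, y) {
  mean(evaluate_node(ind$root, votes) == y)
}

fitness_10fold <- function(ind, votes, y, fold) {
  pred <- evaluate_node(ind$root, votes)
  mean(vapply(seq_len(max(fold)), function(f) {
    mean(pred[fold == f] == y[fold == f])
  }, numeric(1)))
}

tournament_pick <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand[which.max(fitness[cand])]
}

#' Evolve a population of fusion trees
#'
#' Generational GP loop over the terminal pool's cached validation votes.
#' Fitness is an individual's accuracy on the validation partition (or, with
#' `fitness_fold`, the mean per-fold accuracy over a stratified split of the
#' pooled train+validation votes). Each generation keeps the elite, then fills
#' the population with tournament-selected parents passed through crossover
#' (probability `crossover_rate`, pairwise) and point mutation (probability
#' `mutation_rate` per individual).
#'
#' @param cfg a [gp_config()].
#' @param votes matrix of pool votes on the fitness samples
#'   (samples x classifiers).
#' @param y `-1/+1` truth for the fitness samples.
#' @param fitness_fold optional integer fold id per fitness sample; when
#'   given, fitness is the mean per-fold accuracy.
#' @param trace_file optional CSV path receiving per-generation best/mean
#'   fitness.
#' @return list with `population` (final generation, fitnesses set), `best`
#'   (highest-fitness individual), `history` (data.frame generation/best/mean).
#' @export
gp_evolve <- function(cfg, votes, y, fitness_fold = NULL, trace_file = NULL) {
  if (!ncol(votes)) stop("terminal pool is empty")
  pool_size <- ncol(votes)
  score <- function(ind) {
    if (is.null(fitness_fold)) individual_accuracy(ind, votes, y)
    else fitness_10fold(ind, votes, y, fitness_fold)
  }
  pop <- ramped_half_and_half_init(cfg, pool_size)
  fit <- vapply(pop, score, numeric(1))
  for (i in seq_along(pop)) pop[[i]]$fitness <- fit[i]
  history <- data.frame(generation = 0, best = max(fit), mean = mean(fit))
  for (gen in seq_len(cfg$generations)) {
    ord <- order(-fit)
    elite <- pop[ord[seq_len(cfg$elitism)]]
    nxt <- elite
    while (length(nxt) < cfg$pop_size) {
      p1 <- pop[[tournament_pick(fit, cfg$tournament_size)]]
      p2 <- pop[[tournament_pick(fit, cfg$tournament_size)]]
      if (stats::runif(1) < cfg$crossover_rate) {
        off <- gp_crossover(p1, p2, cfg$max_depth)
      } else {
        off <- list(p1, p2)
      }
      for (child in off) {
        if (length(nxt) >= cfg$pop_size) break
        if (stats::runif(1) < cfg$mutation_rate) {
          child <- gp_mutate(child, pool_size, cfg$max_depth)
        }
        nxt[[length(nxt) + 1L]] <- child
      }
    }
    pop <- nxt
    fit <- vapply(pop, score, numeric(1))
    for (i in seq_along(pop)) pop[[i]]$fitness <- fit[i]
    history <- rbind(history, data.frame(generation = gen, best = max(fit), mean = mean(fit)))
  }
  if (!is.null(trace_file)) utils::write.csv(history, trace_file, row.names = FALSE)
  list(population = pop, best = pop[[which.max(fit)]], history = history)
}
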