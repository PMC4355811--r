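all_vote_patterns <- function(k) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
}

node_count_sig <- function(ind) {
  count <- function(node) {
    if (node$kind == "terminal") return(c(0L, 1L))
    Reduce(`+`, lapply(node$children, count)) + c(1L, 0L)
  }
  x <- count(ind$root)
  paste0("ops", x[1], "_terms", x[2])
}

test_that("fusion operators match the exhaustive truth tables", {
  pats <- all_vote_patterns(3)
  for (op in c("Min", "Max", "Average")) {
    node <- gp_operator(op, list(gp_terminal(1), gp_terminal(2), gp_terminal(3)))
    got <- evaluate_node(node, pats)
    want <- apply(pats, 1, function(v) oracle_fuse(op, v))
    expect_equal(unname(got), unname(want), label = op)
  }
  # Min vetoes to -1 even against two positive children
  expect_equal(evaluate_node(gp_operator("Min", list(gp_terminal(1), gp_terminal(2),
                                                     gp_terminal(3))),
                             c(-1, 1, 1)), -1)
  # Max needs only one positive child
  expect_equal(evaluate_node(gp_operator("Max", list(gp_terminal(1), gp_terminal(2),
                                                     gp_terminal(3))),
                             c(-1, -1, 1)), 1)
  # Average is the majority of three
  expect_equal(evaluate_node(gp_operator("Average", list(gp_terminal(1), gp_terminal(2),
                                                         gp_terminal(3))),
                             c(1, 1, -1)), 1)
})

test_that("a two-level seven-tree individual fuses mixed votes to -1", {
  # Average root over two Min blocks and a bare terminal, seven trees in all;
  # with T1, T2 and T5 voting -1 both Min blocks veto to -1 and the majority
  # at the root is negative despite four of seven trees voting +1.
  root <- gp_operator("Average", list(
    gp_operator("Min", list(gp_terminal(1), gp_terminal(2), gp_terminal(3))),
    gp_operator("Min", list(gp_terminal(4), gp_terminal(5), gp_terminal(6))),
    gp_terminal(7)
  ))
  votes <- c(-1, -1, 1, 1, -1, 1, 1)   # T1, T2, T5 negative
  # Min1 = -1, Min2 = -1 (T5), T7 = +1 -> Average(-1, -1, +1) = -1
  expect_equal(evaluate_node(root, votes), -1)
})

test_that("individuals respect the root, arity and depth invariants", {
  t3 <- list(gp_terminal(1), gp_terminal(2), gp_terminal(3))
  expect_error(gp_individual(gp_terminal(1)), "root")
  expect_error(gp_operator("Min", t3[1:2]), "three children")
  deep <- gp_operator("Min", list(
    gp_operator("Min", list(gp_operator("Min", t3), gp_terminal(1), gp_terminal(2))),
    gp_terminal(3), gp_terminal(4)))
  expect_error(gp_individual(deep), "depth")
  expect_s3_class(gp_individual(gp_operator("Average", t3)), "gp_individual")
})

test_that("predict_individual equals the cached-vote shortcut and unanimity", {
  set.seed(50)
  V <- matrix(sample(c(-1, 1), 20 * 8, replace = TRUE), 20, 8)
  ind <- random_individual(8)
  direct <- predict_individual(ind, votes = V)
  expect_equal(direct, evaluate_node(ind$root, V))
  expect_true(all(direct %in% c(-1, 1)))

  # three copies of one classifier under Average reproduce that classifier
  same <- gp_individual(gp_operator("Average",
                                    list(gp_terminal(4), gp_terminal(4), gp_terminal(4))))
  expect_equal(predict_individual(same, votes = V), V[, 4])

  # Min-rooted depth-2 tree: +1 only where all three children are +1
  minr <- gp_individual(gp_operator("Min",
                                    list(gp_terminal(1), gp_terminal(2), gp_terminal(3))))
  expect_equal(predict_individual(minr, votes = V) == 1,
               V[, 1] == 1 & V[, 2] == 1 & V[, 3] == 1)

  expect_error(evaluate_node(gp_terminal(9), V[, 1:3]), "unresolved")
})

test_that("ramped half-and-half fills each (depth, method) cell equally", {
  cfg <- gp_config(pop_size = 80, generations = 1)
  set.seed(60)
  pop <- ramped_half_and_half_init(cfg, pool_size = 12)
  expect_length(pop, 80)
  for (ind in pop) expect_true(assert_valid_individual(ind, 12))

  counts <- table(vapply(pop, function(ind) node_count_sig(ind), character(1)))
  # full depth-2 trees: 1 operator + 3 terminals; full depth-3: 4 operators +
  # 9 terminals; at least 20 of each are guaranteed by the full halves
  expect_gte(counts[["ops1_terms3"]], 20)
  expect_gte(counts[["ops4_terms9"]], 20)
  # depths stay within [2, 3]
  depths <- vapply(pop, function(ind) gpes:::node_depth(ind$root), integer(1))
  expect_true(all(depths %in% 2:3))
  expect_error(ramped_half_and_half_init(cfg, 0), "empty")
})

test_that("crossover and mutation never break the structural invariants", {
  set.seed(70)
  for (i in 1:500) {
    a <- random_individual(10)
    b <- random_individual(10)
    off <- gp_crossover(a, b)
    expect_true(assert_valid_individual(off[[1]], 10))
    expect_true(assert_valid_individual(off[[2]], 10))
    m <- gp_mutate(a, pool_size = 10)
    expect_true(assert_valid_individual(m, 10))
  }
})

test_that("terminal-swap crossover preserves the terminal multiset pairwise", {
  t_a <- gp_individual(gp_operator("Min", list(gp_terminal(1), gp_terminal(2),
                                               gp_terminal(3))))
  t_b <- gp_individual(gp_operator("Max", list(gp_terminal(4), gp_terminal(5),
                                               gp_terminal(6))))
  set.seed(71)
  off <- gp_crossover(t_a, t_b)
  terms <- sort(c(gpes:::terminal_indices(off[[1]]$root),
                  gpes:::terminal_indices(off[[2]]$root)))
  expect_equal(terms, 1:6)
})

test_that("root-operator mutation changes predictions where the operators differ", {
  pats <- all_vote_patterns(3)
  avg <- gp_individual(gp_operator("Average", list(gp_terminal(1), gp_terminal(2),
                                                   gp_terminal(3))))
  min_ <- gp_individual(gp_operator("Min", list(gp_terminal(1), gp_terminal(2),
                                                gp_terminal(3))))
  pa <- predict_individual(avg, votes = pats)
  pm <- predict_individual(min_, votes = pats)
  differing <- which(pa != pm)
  # majority and Min disagree exactly on the three one-negative patterns
  expect_length(differing, 3)
  expect_true(all(rowSums(pats[differing, , drop = FALSE] == -1) == 1))

  # mutating a terminal with a single-entry pool cannot change behaviour
  set.seed(72)
  single <- gp_individual(gp_operator("Average", list(gp_terminal(1), gp_terminal(1),
                                                      gp_terminal(1))))
  mutated <- gp_mutate(single, pool_size = 1)
  V1 <- matrix(sample(c(-1, 1), 10, replace = TRUE), ncol = 1)
  expect_equal(predict_individual(mutated, votes = V1),
               predict_individual(single, votes = V1))
})

test_that("evolution improves fitness, keeps the elite and is reproducible", {
  # pool of 6 noisy classifiers, one perfect: evolution should find fitness 1
  set.seed(80)
  vm <- make_vote_matrix(6, 24, error_rates = c(0.4, 0.4, 0.3, 0.3, 0.2, 0))
  cfg <- gp_config(pop_size = 20, generations = 15)
  run <- function() {
    set.seed(81)
    gp_evolve(cfg, vm$votes, vm$truth)
  }
  a <- run()
  expect_equal(max(a$history$best), 1)
  expect_equal(a$best$fitness, 1)
  # elitism: best fitness never decreases
  expect_true(all(diff(a$history$best) >= 0))
  # fitnesses equal independently recomputed accuracies
  for (ind in a$population[1:5]) {
    expect_equal(ind$fitness, mean(predict_individual(ind, votes = vm$votes) == vm$truth))
  }
  # determinism: identical histories and final predictions
  b <- run()
  expect_identical(a$history, b$history)
  expect_identical(lapply(a$population, function(i) predict_individual(i, votes = vm$votes)),
                   lapply(b$population, function(i) predict_individual(i, votes = vm$votes)))
})
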