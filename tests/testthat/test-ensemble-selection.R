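test_that("majority vote is the sign of the member tally", {
  set.seed(90)
  V <- matrix(sample(c(-1, 1), 30 * 5, replace = TRUE), 30, 5)
  got <- majority_vote(V)
  brute <- apply(V, 1, function(v) if (sum(v == 1) > sum(v == -1)) 1 else -1)
  expect_equal(got, brute)
  # singleton committee is the member itself
  expect_equal(majority_vote(V[, 2, drop = FALSE]), V[, 2])
  # 3 members voting (+1, +1, -1)
  expect_equal(majority_vote(matrix(c(1, 1, -1), 1)), 1)
  expect_error(majority_vote(V[, 1:4]), "odd")
})

test_that("MVE is the tallied misclassification fraction", {
  set.seed(91)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  perfect <- matrix(rep(y, 3), ncol = 3)
  expect_equal(mve(perfect, y), 0)
  # constant +1 committee on a balanced set errs on exactly the negatives
  yb <- rep(c(-1, 1), each = 20)
  expect_equal(mve(matrix(1, 40, 3), yb), 0.5)
  # random 5-member matrix equals the hand tally
  V <- matrix(sample(c(-1, 1), 40 * 5, replace = TRUE), 40, 5)
  hand <- mean(apply(V, 1, function(v) if (sum(v) < 0) -1 else 1) != y)
  expect_equal(mve(V, y), hand)
  expect_error(mve(V[0, ], numeric(0)), "empty")
})

test_that("above-average individual filtering mirrors the candidate rule", {
  mk <- function(a) {
    ind <- gp_individual(gp_operator("Average", list(gp_terminal(1), gp_terminal(2),
                                                     gp_terminal(3))))
    ind$fitness <- a
    ind
  }
  kept <- filter_above_average_individuals(lapply(c(0.9, 0.8, 0.4), mk))
  expect_equal(vapply(kept, `[[`, numeric(1), "fitness"), c(0.9, 0.8))
  expect_length(filter_above_average_individuals(lapply(rep(0.7, 4), mk)), 4)
  expect_length(filter_above_average_individuals(list(mk(0.5))), 1)
  expect_error(filter_above_average_individuals(list()), "empty")
})

test_that("forward search agrees with the naive oracle on small candidate sets", {
  set.seed(92)
  for (i in 1:25) {
    L <- sample(3:7, 1)
    n <- sample(c(11, 15, 21), 1)
    vm <- make_vote_matrix(L, n, error_rates = runif(L, 0.05, 0.45))
    got <- forward_search(vm$votes, vm$truth)
    want <- oracle_forward_search(vm$votes, vm$truth)
    expect_equal(got$members, want$members)
    expect_equal(got$trace, want$trace)
  }
})

test_that("forward search honours its stopping and size contracts", {
  set.seed(93)
  for (i in 1:30) {
    L <- sample(3:12, 1)
    vm <- make_vote_matrix(L, 15, error_rates = runif(L, 0, 0.5))
    com <- forward_search(vm$votes, vm$truth)
    expect_equal(length(com$members) %% 2, 1)            # always odd
    expect_lte(length(com$members), L)
    expect_true(all(diff(com$trace) <= 0))               # non-increasing trace
    if (!is.na(com$rejected_mve)) {
      expect_gt(com$rejected_mve, com$trace[length(com$trace)])
    }
  }

  # identical candidates: MVE never worsens, so the search exhausts the set
  base <- make_vote_matrix(1, 15, error_rates = 0.2, seed = 5)
  V <- matrix(rep(base$votes, 7), ncol = 7)
  com <- forward_search(V, base$truth)
  expect_equal(length(com$members), 7)
  expect_equal(unique(com$trace), mve(V[, 1, drop = FALSE], base$truth))

  # a perfect candidate starts the committee; pairs of clones of it keep MVE
  # at zero so they are accepted until exhaustion
  vm <- make_vote_matrix(5, 20, error_rates = c(0.3, 0, 0, 0, 0.3), seed = 6)
  com2 <- forward_search(vm$votes, vm$truth)
  expect_equal(com2$trace[1], 0)
  expect_equal(com2$trace[length(com2$trace)], 0)
  expect_error(forward_search(matrix(numeric(0), 5, 0), rep(1, 5)), "no candidates")
})

test_that("committee prediction is the member-wise majority", {
  set.seed(94)
  V <- matrix(sample(c(-1, 1), 18 * 9, replace = TRUE), 18, 9)
  committee <- lapply(1:3, function(i) {
    gp_individual(gp_operator("Average", lapply(sample(9, 3), gp_terminal)))
  })
  got <- predict_committee(committee, votes = V)
  member <- vapply(committee, function(ind) predict_individual(ind, votes = V),
                   numeric(18))
  expect_equal(got, majority_vote(member))
  # singleton committee
  expect_equal(predict_committee(committee[1], votes = V),
               predict_individual(committee[[1]], votes = V))
})

test_that("operator frequencies sum to one over committee members", {
  committee <- list(
    gp_individual(gp_operator("Min", list(gp_terminal(1), gp_terminal(2), gp_terminal(3)))),
    gp_individual(gp_operator("Average", list(
      gp_operator("Max", list(gp_terminal(1), gp_terminal(2), gp_terminal(3))),
      gp_terminal(4), gp_terminal(5))))
  )
  freq <- operator_frequencies(committee)
  expect_equal(sum(freq), 1)
  expect_equal(unname(freq), c(1 / 3, 1 / 3, 1 / 3))
  expect_named(freq, c("Min", "Average", "Max"))
})
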