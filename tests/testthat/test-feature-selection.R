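make_informative_matrix <- function(seed = 3, n = 40, p = 100, informative = c(7, 23),
                                    shift = 2) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  for (j in informative) X[, j] <- X[, j] + shift * y
  list(X = X, y = y, informative = informative)
}

test_that("f_test ranking matches the one-way ANOVA oracle", {
  fx <- make_informative_matrix()
  got <- run_selector("f_test", fx$X, fx$y, k = 10)
  oracle <- order(-oracle_f_stats(fx$X, fx$y), seq_len(ncol(fx$X)))[1:10]
  expect_equal(as.integer(got), oracle)
  # the two informative features outrank all 98 noise features
  expect_setequal(as.integer(run_selector("f_test", fx$X, fx$y, k = 2)),
                  fx$informative)
})

test_that("every selector returns k unique valid indices and finds signal", {
  fx <- make_informative_matrix(shift = 3)
  for (m in c("f_test", "relief", "random_forest", "svm_rfe")) {
    set.seed(11)
    idx <- as.integer(run_selector(m, fx$X, fx$y, k = 10))
    expect_length(idx, 10)
    expect_false(anyDuplicated(idx) > 0)
    expect_true(all(idx >= 1 & idx <= ncol(fx$X)))
    expect_true(all(fx$informative %in% idx),
                label = paste(m, "recovers the informative features"))
  }
  # k = feature count returns everything
  small <- make_informative_matrix(p = 12, informative = c(1, 2))
  for (m in c("f_test", "relief", "random_forest", "svm_rfe")) {
    set.seed(12)
    expect_setequal(as.integer(run_selector(m, small$X, small$y, k = 12)), 1:12)
  }
  expect_error(run_selector("f_test", fx$X, fx$y, k = 101), "exceeds")
  expect_error(run_selector("f_test", fx$X, rep(1, 40), k = 5), "one class")
})

test_that("svm_rfe removes two features per iteration", {
  fx <- make_informative_matrix(p = 10, informative = c(1, 2))
  got <- run_selector("svm_rfe", fx$X, fx$y, k = 4)
  # 10 -> 8 -> 6 -> 4: exactly three elimination rounds
  expect_equal(attr(got, "n_iterations"), 3L)
  expect_length(got, 4)
  # odd gap: the last round removes only one feature
  got2 <- run_selector("svm_rfe", fx$X, fx$y, k = 5)
  expect_length(got2, 5)
  expect_equal(attr(got2, "n_iterations"), 3L)
})

test_that("f_test selection is equivariant under feature permutation", {
  fx <- make_informative_matrix()
  perm <- sample(ncol(fx$X))
  base <- as.integer(run_selector("f_test", fx$X, fx$y, k = 15))
  permuted <- as.integer(run_selector("f_test", fx$X[, perm], fx$y, k = 15))
  expect_equal(match(base, perm), permuted)
})

test_that("feature pool is the deduplicated first-seen union within [k, 4k]", {
  fx <- make_informative_matrix(n = 30, p = 300, informative = c(5, 50), shift = 3)
  set.seed(21)
  pool <- build_feature_pool(fx$X, fx$y, k_per_method = 50)
  expect_s3_class(pool, "feature_pool")
  expect_gte(length(pool$indices), 50)
  expect_lte(length(pool$indices), 200)
  expect_false(anyDuplicated(pool$indices) > 0)
  expect_equal(pool$indices,
               unique(unlist(lapply(pool$per_method, as.integer), use.names = FALSE)))
  expect_named(pool$per_method,
               c("f_test", "relief", "random_forest", "svm_rfe"))
  # provenance lists each pooled index under the methods that chose it
  first <- pool$indices[1]
  expect_true("f_test" %in% pool$provenance[[as.character(first)]])

  # full-overlap lower bound: four copies of the same selector
  set.seed(22)
  p_same <- build_feature_pool(fx$X, fx$y, k_per_method = 50,
                               selectors = rep("f_test", 4))
  expect_length(p_same$indices, 50)

  # zero-overlap upper bound: four forced-disjoint 50-feature lists
  disjoint <- pool_from_lists(list(a = 1:50, b = 51:100, c = 101:150, d = 151:200))
  expect_length(disjoint$indices, 200)
  # forced full overlap collapses to one list
  overlap <- pool_from_lists(list(a = 1:50, b = 1:50, c = 1:50, d = 50:1))
  expect_length(overlap$indices, 50)
  expect_equal(overlap$provenance[["1"]], c("a", "b", "c", "d"))
})

test_that("pool serialization to JSON preserves indices and per-method lists", {
  fx <- make_informative_matrix(p = 60, informative = c(1, 2))
  set.seed(31)
  pool <- build_feature_pool(fx$X, fx$y, k_per_method = 10)
  p <- withr::local_tempfile(fileext = ".json")
  write_feature_pool(pool, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$indices, pool$indices)
  expect_equal(back$per_method$f_test, as.integer(pool$per_method$f_test))
})
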