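# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small well-separated two-class dataset (binary pipeline fixture)
tiny_binary <- function(seed = 42, n_per_class = c(20, 20), n_features = 200,
                        n_informative = 8, shift = 4) {
  make_dataset(synthetic_spec(n_per_class = n_per_class, n_features = n_features,
                              n_informative = n_informative, shift = shift),
               seed = seed)
}

# write a 4x3 delimited table with a label column; returns the path
write_tiny_table <- function(path, sep = ",") {
  header <- paste(c("id", "g1", "g2", "g3", "label"), collapse = sep)
  rows <- c(
    paste(c("s1", "1.0", "2.0", "3.0", "A"), collapse = sep),
    paste(c("s2", "1.5", "2.5", "3.5", "A"), collapse = sep),
    paste(c("s3", "4.0", "5.0", "6.0", "B"), collapse = sep),
    paste(c("s4", "4.5", "5.5", "6.5", "B"), collapse = sep)
  )
  writeLines(c(header, rows), path)
  path
}

# independent oracle: one-way ANOVA F per feature via stats::oneway.test
oracle_f_stats <- function(X, y) {
  apply(X, 2, function(col) {
    stats::oneway.test(col ~ factor(y), var.equal = TRUE)$statistic
  })
}

# independent oracle for the three fusion operators on one vote triple
oracle_fuse <- function(op, v) {
  switch(op,
    Min = if (any(v == -1)) -1 else 1,
    Max = if (any(v == 1)) 1 else -1,
    Average = if (mean(v) < 0) -1 else 1
  )
}

# independent naive forward search: plain loops, no shared code with the
# implementation under test
oracle_forward_search <- function(V, y, acc = colMeans(V == y)) {
  naive_mve <- function(cols) {
    wrong <- 0
    for (s in seq_along(y)) {
      tally <- sum(V[s, cols])
      pred <- if (tally < 0) -1 else 1
      if (pred != y[s]) wrong <- wrong + 1
    }
    wrong / length(y)
  }
  members <- which(acc == max(acc))[1]
  remaining <- setdiff(seq_len(ncol(V)), members)
  current <- naive_mve(members)
  trace <- current
  repeat {
    if (length(remaining) < 2) break
    best_pair <- NULL; best_mve <- Inf; best_acc <- -Inf
    for (i in seq_along(remaining)) {
      for (j in seq_along(remaining)) {
        if (j <= i) next
        p <- c(remaining[i], remaining[j])
        m <- naive_mve(c(members, p))
        a <- acc[p[1]] + acc[p[2]]
        if (m < best_mve || (m == best_mve && a > best_acc)) {
          best_pair <- p; best_mve <- m; best_acc <- a
        }
      }
    }
    if (best_mve > current) break
    members <- c(members, best_pair)
    remaining <- setdiff(remaining, best_pair)
    current <- best_mve
    trace <- c(trace, current)
  }
  list(members = members, trace = trace)
}

# random valid GP individual for property sweeps
random_individual <- function(pool_size, max_depth = 3) {
  cfg <- gp_config(pop_size = 4, generations = 1, init_depths = 2:max_depth,
                   max_depth = max_depth)
  ramped_half_and_half_init(cfg, pool_size)[[sample.int(4, 1)]]
}

# structural validity check used by the property sweeps
assert_valid_individual <- function(ind, pool_size, max_depth = 3) {
  check_node <- function(node, depth) {
    if (depth > max_depth) return(FALSE)
    if (node$kind == "terminal") {
      return(node$index >= 1 && node$index <= pool_size)
    }
    if (length(node$children) != 3) return(FALSE)
    all(vapply(node$children, check_node, logical(1), depth + 1))
  }
  ind$root$kind == "nonterminal" && check_node(ind$root, 1)
}
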