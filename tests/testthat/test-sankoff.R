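test_that("Sankoff minimum costs match exhaustive enumeration on known cases", {
  tr <- parse_tree("((A,B),(C,D));")
  expect_equal(sankoff_cost(tr, c(A = 0, B = 0, C = 2, D = 2)), 2)
  expect_equal(sankoff_cost(parse_tree("((A,B),C);"), c(A = 0, B = 1, C = 3)), 3)
  expect_equal(sankoff_cost(tr, c(A = 5, B = 5, C = 5, D = 5)), 0)
  # polytomy handled by the DP directly
  expect_equal(sankoff_cost(parse_tree("(A,B,C,D);"),
                            c(A = 0, B = 0, C = 0, D = 3)), 3)
})

test_that("missing leaf states are absence by default, an error in strict mode", {
  tr <- parse_tree("((A,B),C);")
  expect_equal(sankoff_cost(tr, c(A = 1, B = 1)), 1)  # C -> state 0
  expect_error(sankoff_cost(tr, c(A = 1, B = 1), missing_as_zero = FALSE),
               "without a state")
  expect_error(sankoff_cost(tr, c(A = 40, B = 1, C = 1)), "0..35")
})

test_that("unambiguous changes require agreement across every MPR", {
  tr <- parse_tree("((A,B),(C,D));")
  # the single change sits on different branches in different MPRs
  expect_equal(nrow(unambiguous_changes(tr, c(A = 0, B = 0, C = 1, D = 1))), 0)
  ch <- unambiguous_changes(tr, c(A = 0, B = 0, C = 0, D = 1))
  expect_equal(nrow(ch), 1)
  expect_equal(ch$label, "D")
  expect_equal(c(ch$from, ch$to), c(0, 1))
  expect_equal(nrow(unambiguous_changes(tr, c(A = 2, B = 2, C = 2, D = 2))), 0)
})

test_that("DP, enumeration and final-set criteria agree with brute force", {
  set.seed(303)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    tr <- random_tree(n)
    max_state <- sample(2:5, 1)
    st <- setNames(sample(0:max_state, n, replace = TRUE), tr$tip.label)
    want <- oracle_sankoff(tr, st, max_state)
    fit <- sankoff_fit(tr, st)
    expect_equal(fit$min_cost, want$min_cost)
    expect_equal(fit$n_mpr, want$n_mpr)
    got <- unambiguous_changes(tr, st)                  # enumeration path
    got_fs <- unambiguous_changes(tr, st, mpr_limit = 0) # final-set fallback
    expect_true(isTRUE(attr(got_fs, "approximate")))
    key <- function(d) sort(paste(d$parent, d$node, d$from, d$to))
    expect_equal(key(got), key(want$changes))
    expect_equal(key(got_fs), key(got))
    # explicit MPR list: every reconstruction attains the minimum cost
    mprs <- enumerate_mprs(fit)
    cost <- rowSums(abs(mprs[, fit$edge[, 1], drop = FALSE] -
                          mprs[, fit$edge[, 2], drop = FALSE]))
    expect_true(all(cost == fit$min_cost))
    # leaf final sets are singletons of the observed states
    for (tip in seq_len(n))
      expect_equal(fit$final_sets[[tip]], unname(st[tr$tip.label[tip]]))
  }
})

test_that("Sankoff cost agrees with phangorn's implementation", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    max_state <- 4
    st <- setNames(sample(0:max_state, n, replace = TRUE), tr$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = as.character(0:max_state))
    cost <- ordered_cost_matrix(max_state + 1)
    dimnames(cost) <- list(0:max_state, 0:max_state)
    want <- phangorn::parsimony(tr, dat, method = "sankoff", cost = cost)
    expect_equal(sankoff_cost(tr, st), unname(want))
  }
})

test_that("step matrices sum unambiguous changes and are additive", {
  tr <- parse_tree("((A,B),(C,D));")
  cm1 <- make_cm(matrix(c(0L, 0L, 0L, 1L), 4, 1), taxa = c("A", "B", "C", "D"))
  sm1 <- build_step_matrix(tr, cm1, "helical")
  expect_equal(sm1$counts["0", "1"], 1L)
  expect_equal(sum(sm1$counts), 1L)

  cm2 <- make_cm(matrix(c(0L, 0L, 0L, 1L), 4, 2), taxa = c("A", "B", "C", "D"))
  sm2 <- build_step_matrix(tr, cm2, "helical")
  expect_equal(sm2$counts["0", "1"], 2L)
  expect_equal((sm1 + sm1)$counts, sm2$counts)

  cm3 <- make_cm(matrix(3L, 4, 2), taxa = c("A", "B", "C", "D"))
  expect_equal(sum(build_step_matrix(tr, cm3, "helical")$counts), 0L)
})

test_that("step-matrix additivity holds on random character sets", {
  set.seed(77)
  tr <- random_tree(8)
  vals <- matrix(sample(0:5, 8 * 6, replace = TRUE), 8, 6)
  cm_all <- make_cm(vals, taxa = tr$tip.label)
  total <- build_step_matrix(tr, cm_all, "helical")$counts
  acc <- matrix(0L, 36, 36)
  for (j in 1:6) {
    cmj <- make_cm(vals[, j, drop = FALSE], taxa = tr$tip.label)
    acc <- acc + build_step_matrix(tr, cmj, "helical")$counts
  }
  expect_equal(unname(total), unname(acc))
})

test_that("bubble export writes symbols, counts and frequencies", {
  tr <- parse_tree("((A,B),(C,D));")
  cm <- make_cm(matrix(c(0L, 0L, 0L, 1L), 4, 2), taxa = c("A", "B", "C", "D"))
  bub <- export_bubble(build_step_matrix(tr, cm, "helical"))
  expect_equal(bub$from, "0")
  expect_equal(bub$to, "1")
  expect_equal(bub$count, 2L)
  expect_equal(bub$frequency, 1.0)  # per-character average over 2 characters

  # zero matrix -> no rows
  cm0 <- make_cm(matrix(2L, 4, 1), taxa = c("A", "B", "C", "D"))
  expect_equal(nrow(export_bubble(build_step_matrix(tr, cm0, "helical"))), 0)

  # symbol labels beyond 9
  cmA <- make_cm(matrix(c(10L, 10L, 10L, 11L), 4, 1),
                 taxa = c("A", "B", "C", "D"))
  bubA <- export_bubble(build_step_matrix(tr, cmA, "helical",
                                          normalization = "raw"))
  expect_equal(bubA$from, "A")
  expect_equal(bubA$to, "B")
  expect_equal(bubA$frequency, 1L)
})

test_that("taxon/leaf mismatches are reported with offenders", {
  tr <- parse_tree("((A,B),(C,D));")
  cm <- make_cm(matrix(0L, 3, 1), taxa = c("A", "B", "X"))
  expect_error(build_step_matrix(tr, cm, "helical"), "X")
})
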