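test_that("accretion histories follow the generating law and are reproducible", {
  cfg <- synthetic_config(A_true = 13.56, c_true = 0.490, noise_sd = 0)
  h <- gen_accretion_history(cfg)
  expect_equal(h$series$mean_length[h$series$x == 1],
               13.56 * exp(-0.490), tolerance = 1e-12)
  expect_equal(ape::Ntip(h$tree), cfg$n_sub)
  # determinism
  h2 <- gen_accretion_history(cfg)
  expect_identical(h$series, h2$series)
  # c = 0, no noise: constant at A (no flooring involved)
  flat <- gen_accretion_history(synthetic_config(A_true = 7, c_true = 0,
                                                 noise_sd = 0))
  expect_true(all(flat$series$mean_length == 7))
  # ties at the deepest cherry share their accretion rank
  expect_equal(sum(h$series$x == max(h$series$x)), 2)
  expect_error(synthetic_config(n_sub = 2), "config error")
  expect_error(synthetic_config(A_true = -1), "config error")
})

test_that("present substructure lengths are floored at 1", {
  h <- gen_accretion_history(synthetic_config(A_true = 2, c_true = 1,
                                              noise_sd = 0.5, seed = 4))
  expect_true(all(h$series$mean_length >= 1))
})

test_that("stepwise character simulation respects rate, bounds and seed", {
  tr <- pectinate_tree(20)
  s0 <- simulate_ordered_character(tr, 7, 0, seed = 1)
  expect_true(all(s0 == 7))
  expect_error(simulate_ordered_character(tr, 99, 0.1), "0..35")
  # reflection keeps the walk inside the alphabet
  for (seed in 1:20) {
    lo <- simulate_ordered_character(tr, 0, 2, seed = seed)
    hi <- simulate_ordered_character(tr, 35, 2, seed = seed)
    expect_true(all(lo >= 0 & lo <= 35))
    expect_true(all(hi >= 0 & hi <= 35))
  }
  expect_identical(simulate_ordered_character(tr, 5, 0.5, seed = 9),
                   simulate_ordered_character(tr, 5, 0.5, seed = 9))
})

test_that("parsimony undercounts the true number of simulated steps", {
  set.seed(31)
  tr <- ape::rtree(12)
  for (rep in 1:200) {
    st <- simulate_ordered_character(tr, 10, 0.5)
    expect_lte(sankoff_cost(tr, st), attr(st, "total_steps"))
  }
})

test_that("molecule sets are self-checking and byte-reproducible", {
  cfg <- synthetic_config(n_sub = 5, n_taxa = 12, seed = 8)
  mols <- gen_molecule_set(cfg)
  expect_length(mols$structures, 12)
  f1 <- withr::local_tempfile(fileext = ".dbn")
  f2 <- withr::local_tempfile(fileext = ".dbn")
  writeLines(unlist(lapply(mols$structures, write_structure, "dotbracket")), f1)
  mols2 <- gen_molecule_set(cfg)
  writeLines(unlist(lapply(mols2$structures, write_structure, "dotbracket")), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("absent substructures are coded with the minimum state 0", {
  cfg <- synthetic_config(n_sub = 5, n_taxa = 30, seed = 2)
  mols <- gen_molecule_set(cfg)
  absent <- rownames(mols$lengths)[mols$lengths[, "S5"] == 0]
  expect_gt(length(absent), 0)  # the variable 3' unit drops in some taxa
  cm <- build_character_matrix(lapply(mols$structures, decompose))
  expect_true(all(cm$states[absent, "S5"] == "0"))
  expect_true(all(cm$states[absent, "HL5"] == "0"))
})

test_that("coding the molecule set reproduces the generating lengths exactly", {
  cfg <- synthetic_config(n_sub = 6, n_taxa = 15, seed = 13)
  mols <- gen_molecule_set(cfg)
  cm <- build_character_matrix(lapply(mols$structures, decompose))
  ml <- mean_lengths(cm)
  for (k in seq_len(nrow(ml))) {
    intended <- mols$lengths[, ml$label[k]]
    expect_equal(ml$mean_length[k], mean(intended[intended > 0]),
                 info = ml$label[k])
    expect_equal(ml$class[k], unname(mols$classes[ml$label[k]]))
  }
})
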