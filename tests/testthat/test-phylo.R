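test_that("newick reading validates and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)[1:3]), 2)

  expect_error(read_newick("((A:1,A:1):1,C:2);", text = TRUE), "duplicate")
  expect_error(read_newick("((A:1,B:1", text = TRUE))
  expect_error(read_newick("((A,B),C);", text = TRUE), "branch lengths")
  imp <- read_newick("((A,B),C);", text = TRUE, impute_length = 1)
  expect_equal(imp$edge.length, rep(1, nrow(imp$edge)))

  # write-then-read preserves topology, labels and lengths on random trees
  for (s in 1:50) {
    t0 <- random_fixture_tree(sample(4:20, 1), seed = s)
    t1 <- read_newick(write_newick(t0), text = TRUE)
    expect_setequal(t1$tip.label, t0$tip.label)
    d0 <- ape::cophenetic.phylo(t0)
    d1 <- ape::cophenetic.phylo(t1)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-8)
  }
})

test_that("tip substitution relabels stand-ins without touching the tree", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  sub <- substitute_tips(tr, data.frame(missing_species = "D", stand_in = "C"))
  expect_setequal(sub$tip.label, c("A", "B", "D"))
  expect_equal(sub$edge.length, tr$edge.length)

  expect_identical(substitute_tips(tr, data.frame(missing_species = character(0),
                                                  stand_in = character(0))),
                   tr)
  expect_error(substitute_tips(tr, data.frame(missing_species = "D",
                                              stand_in = "Z")), "Z")
  expect_error(substitute_tips(tr, data.frame(missing_species = "A",
                                              stand_in = "C")), "already present")

  # batch substitutions preserve distances among untouched tips
  big <- random_fixture_tree(78, seed = 99)
  stand_ins <- paste0("t", seq(1, 78, by = 8))[1:10]
  tab <- data.frame(missing_species = paste0("new", 1:10), stand_in = stand_ins)
  sub2 <- substitute_tips(big, tab)
  untouched <- setdiff(big$tip.label, stand_ins)
  d_before <- ape::cophenetic.phylo(big)[untouched, untouched]
  d_after <- ape::cophenetic.phylo(sub2)[untouched, untouched]
  expect_equal(d_after, d_before)
})

test_that("population expansion keeps within-species correlation at 1 and other distances intact", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  ex <- expand_populations(tr, list(A = c("A_1", "A_2")), epsilon = 1e-6)
  R <- bm_correlation(ex)
  expect_gte(R["A_1", "A_2"], 1 - 1e-5)
  expect_equal(R["A_1", "B"], R["A_2", "B"])

  # all-singleton multiplicity is just a relabeling
  ex1 <- expand_populations(tr, list(A = "A_x", C = "C_x"))
  expect_setequal(ex1$tip.label, c("A_x", "B", "C_x"))
  expect_equal(ape::cophenetic.phylo(ex1)["A_x", "C_x"],
               ape::cophenetic.phylo(tr)["A", "C"])

  # restricting to one population per species recovers the unexpanded matrix
  big <- random_fixture_tree(12, seed = 4)
  mult <- setNames(lapply(big$tip.label, function(t) paste0(t, "_", 1:3)),
                   big$tip.label)
  exb <- expand_populations(big, mult, epsilon = 1e-6)
  Rb <- bm_correlation(exb)
  one_per <- paste0(big$tip.label, "_1")
  R0 <- bm_correlation(big)
  expect_equal(unname(Rb[one_per, one_per]), unname(R0[big$tip.label, big$tip.label]),
               tolerance = 1e-5)

  expect_error(expand_populations(tr, list(A = c("B", "A_2"))), "collide")
  expect_error(expand_populations(tr, list(A = c("A_1", "A_2")), epsilon = 1e-4),
               "epsilon")
})

test_that("pruning preserves pairwise tip distances exactly", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  pr <- prune_to(tr, c("A", "B"))
  expect_setequal(pr$tip.label, c("A", "B"))
  expect_equal(ape::cophenetic.phylo(pr)["A", "B"], 2)

  expect_identical(prune_to(tr, c("C", "A", "B")), tr)
  expect_error(prune_to(tr, c("A", "Q")), "Q")

  t20 <- random_fixture_tree(20, seed = 12)
  keep <- sample(t20$tip.label, 8)
  p8 <- prune_to(t20, keep)
  d_full <- tip_distances_bruteforce(t20)[keep, keep]
  d_sub <- tip_distances_bruteforce(p8)[keep, keep]
  expect_equal(d_sub, d_full, tolerance = 1e-10)
})

test_that("Brownian-motion correlation matches the shared-path oracle and is PSD", {
  # star tree: no shared path, identity matrix
  star <- read_newick("(A:1,B:1,C:1,D:1);", text = TRUE)
  expect_equal(unname(bm_correlation(star)), diag(4))

  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  R <- bm_correlation(tr)
  expect_equal(R["A", "B"], 0.5)
  expect_equal(R["A", "C"], 0)
  expect_equal(R["B", "C"], 0)

  for (s in 1:5) {
    t30 <- random_fixture_tree(30, seed = 300 + s)
    R <- bm_correlation(t30)
    expect_equal(R, bm_correlation_bruteforce(t30)[rownames(R), colnames(R)],
                 tolerance = 1e-10)
    expect_equal(R, t(R))
    expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("correlation is scale-invariant, order-equivariant, and depth-normalized", {
  t15 <- random_fixture_tree(15, seed = 21)
  R1 <- bm_correlation(t15)
  t15b <- t15
  t15b$edge.length <- t15$edge.length * 7.3
  expect_equal(bm_correlation(t15b), R1, tolerance = 1e-12)

  # permuting tips permutes rows/columns
  rot <- ape::rotate(t15, node = 16L)
  R2 <- bm_correlation(rot)
  expect_equal(R2[rownames(R1), colnames(R1)], R1, tolerance = 1e-12)

  # ultrametric case: R_ij = depth(MRCA)/total depth
  ul <- read_newick("((A:1,B:1):2,(C:2,D:2):1);", text = TRUE)
  Ru <- bm_correlation(ul)
  expect_equal(Ru["A", "B"], 2 / 3)
  expect_equal(Ru["C", "D"], 1 / 3)
  expect_equal(Ru["A", "C"], 0)

  # zero-depth tip is an error
  expect_error(bm_correlation(read_newick("(A:0,B:1);", text = TRUE)),
               "zero-depth")
})
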