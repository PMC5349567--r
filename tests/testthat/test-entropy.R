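test_that("branch frequencies: equal weighting neutralizes read depth", {
  tr <- parse_tree("(A:1,B:1);")
  g <- new_grouping(c(s1 = "g1", s2 = "g2"))
  balanced <- matrix(c(10L, 0L, 0L, 10L), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  skewed <- matrix(c(100L, 0L, 0L, 10L), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  for (cnt in list(balanced, skewed)) {
    ba <- branch_frequencies(tr, cnt, g)
    expect_equal(unname(ba$p_i), c(0.5, 0.5))
    expect_equal(unname(ba$p_ig["A", ]), c(0.5, 0))
  }
  # read-proportional weighting is depth-sensitive by design
  bp <- branch_frequencies(tr, skewed, g, weighting = "proportional")
  expect_equal(unname(bp$p_i), c(100, 10) / 110)
})

test_that("internal branch frequency equals the sum of its children", {
  tr <- parse_tree("((A:1,B:1)N:1,C:2);")
  g <- new_grouping(c(s1 = "g1"))
  cnt <- matrix(c(5L, 5L, 0L), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  ba <- branch_frequencies(tr, cnt, g)
  expect_equal(unname(ba$p_i[ba$label == "N"]), 1)
  # general descent consistency on random instances
  for (seed in 1:20) {
    inst <- random_instance(seed)
    ba <- branch_frequencies(inst$tree, inst$counts, inst$grouping)
    for (k in which(ba$node > ba$bi$n_tip)) {
      kids <- which(ba$parent == ba$node[k])
      expect_equal(unname(ba$p_i[k]), sum(ba$p_i[kids]), tolerance = 1e-12)
    }
  }
})

test_that("gamma entropy matches the brute-force value on a worked example", {
  # tree ((A:1,B:1):1,C:2), abundances A=B=0.25, C=0.5:
  # T_bar = 2 and H = 0.8664339756999316 by direct summation over the
  # four branches (frozen from the first-principles oracle)
  tr <- parse_tree("((A:1,B:1):1,C:2);")
  g <- new_grouping(c(s1 = "g1"))
  cnt <- matrix(c(25L, 25L, 50L), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  ba <- branch_frequencies(tr, cnt, g)
  expect_equal(ba$T_bar, 2)
  gam <- gamma_entropy(ba)
  expect_equal(gam$H_gamma, 0.8664339756999316, tolerance = 1e-12)
  orc <- oracle_partition(tr, cnt, g)
  expect_equal(gam$H_gamma, orc$H_gamma, tolerance = 1e-12)
})

test_that("single-leaf community has zero entropy, unit diversity", {
  tr <- parse_tree("(A:1,B:1);")
  g <- new_grouping(c(s1 = "g1"))
  cnt <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  gam <- gamma_entropy(branch_frequencies(tr, cnt, g))
  expect_equal(gam$H_gamma, 0)
  expect_equal(gam$D_gamma, 1)
})

test_that("per-group diversities: exclusive equal star groups give D_g = n", {
  tr <- simulate_tree(8, "star")
  cnt <- matrix(0L, 8, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  cnt[1:4, 1] <- 10L
  cnt[5:8, 2] <- 10L
  g <- new_grouping(c(s1 = "g1", s2 = "g2"))
  alp <- alpha_entropy(branch_frequencies(tr, cnt, g))
  expect_equal(unname(alp$D_group), c(4, 4), tolerance = 1e-12)
})

test_that("beta: identical groups give zero, disjoint groups give ln(2)", {
  tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
  g <- new_grouping(c(s1 = "g1", s2 = "g2"))
  same <- matrix(c(4L, 3L, 2L, 1L, 8L, 6L, 4L, 2L), 4,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  p_same <- phylo_partition(tr, same, g)
  expect_equal(p_same$H_beta, 0, tolerance = 1e-12)
  expect_true(all(abs(p_same$branch_beta) < 1e-12))
  expect_equal(p_same$H_alpha, p_same$H_gamma, tolerance = 1e-12)

  disj <- matrix(c(10L, 10L, 0L, 0L, 0L, 0L, 10L, 10L), 4,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  p_disj <- phylo_partition(tr, disj, g)
  expect_equal(p_disj$H_beta, log(2), tolerance = 1e-12)
  expect_equal(p_disj$turnover, 1, tolerance = 1e-12)
  occupied <- p_disj$ba$p_i > 0
  expect_true(all(p_disj$branch_beta[occupied] > 0))
})

test_that("a branch shared at equal conditional frequencies contributes zero", {
  tr <- parse_tree("((A:1,B:1)N:1,(C:1,D:1)M:1);")
  g <- new_grouping(c(s1 = "g1", s2 = "g2"))
  # clade N occupies 40% of both groups; C/D differ between groups
  cnt <- matrix(c(20L, 20L, 60L, 0L, 10L, 10L, 0L, 30L), 4,
                dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  p <- phylo_partition(tr, cnt, g)
  expect_equal(unname(p$branch_beta[names(p$branch_beta) == "N"]), 0, tolerance = 1e-12)
  # clade M also holds 60% of both groups, but its members C and D are
  # group-exclusive, so the leaf branches carry the signal
  expect_equal(unname(p$branch_beta[names(p$branch_beta) == "M"]), 0, tolerance = 1e-12)
  expect_gt(unname(p$branch_beta[names(p$branch_beta) == "C"]), 0)
  expect_gt(unname(p$branch_beta[names(p$branch_beta) == "D"]), 0)
})

test_that("beta requires at least two groups", {
  tr <- parse_tree("(A:1,B:1);")
  g <- new_grouping(c(s1 = "only"))
  cnt <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  ba <- branch_frequencies(tr, cnt, g)
  expect_error(beta_mutual_information(ba), "single group")
  expect_error(turnover(0.1, g), "single group")
})

test_that("partition is invariant to sample column order", {
  inst <- random_instance(99)
  p1 <- phylo_partition(inst$tree, inst$counts, inst$grouping)
  perm <- sample(ncol(inst$counts))
  p2 <- phylo_partition(inst$tree, inst$counts[, perm, drop = FALSE], inst$grouping)
  expect_equal(p1$H_gamma, p2$H_gamma, tolerance = 1e-12)
  expect_equal(p1$H_beta, p2$H_beta, tolerance = 1e-12)
})

test_that("entropies are invariant to global branch-length rescaling", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    p1 <- phylo_partition(inst$tree, inst$counts, inst$grouping)
    scaled <- inst$tree
    scaled$edge.length <- scaled$edge.length * 37.5
    p2 <- phylo_partition(scaled, inst$counts, inst$grouping)
    expect_equal(p1$H_gamma, p2$H_gamma, tolerance = 1e-12)
    expect_equal(p1$H_alpha, p2$H_alpha, tolerance = 1e-12)
    expect_equal(p1$H_beta, p2$H_beta, tolerance = 1e-12)
  }
})

test_that("beta is bounded by the grouping entropy", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    p <- phylo_partition(inst$tree, inst$counts, inst$grouping)
    expect_gte(p$H_beta, -1e-12)
    expect_lte(p$H_beta, p$H_G + 1e-12)
    expect_gte(p$turnover, -1e-12)
    expect_lte(p$turnover, 1 + 1e-12)
  }
})

test_that("branch table and partition outputs are consistent", {
  inst <- random_instance(7)
  p <- phylo_partition(inst$tree, inst$counts, inst$grouping)
  bt <- branch_table(p)
  expect_equal(nrow(bt), p$n_branches)
  expect_equal(sum(bt$contribution_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(bt$H_beta_i), p$H_beta, tolerance = 1e-12)
  d <- file.path(tempdir(), "partition_out")
  paths <- write_partition(p, d)
  s <- jsonlite::read_json(paths[[1]])
  expect_equal(s$H_gamma, p$H_gamma, tolerance = 1e-9)
  expect_equal(s$turnover, p$turnover, tolerance = 1e-9)
})
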