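make_counts <- function(totals, samples = c("s1", "s2")) {
  n <- length(totals)
  m <- matrix(0L, n, length(samples),
              dimnames = list(names(totals), samples))
  m[, 1] <- as.integer(ceiling(totals / 2))
  m[, 2] <- as.integer(totals) - m[, 1]
  m
}

test_that("min-count filter removes exactly the OTUs below threshold", {
  cnt <- make_counts(c(a = 10, b = 74, c = 75, d = 1000))
  kept <- filter_min_count(cnt, 75)
  expect_identical(rownames(kept), c("c", "d"))
  expect_identical(filter_min_count(cnt, 0), cnt)
  expect_error(filter_min_count(cnt, 1e6), "below the count threshold")
})

test_that("taxa subsetting keeps CP/CPR lineages and drops the rest", {
  cnt <- make_counts(c(o1 = 100, o2 = 100, o3 = 100, o4 = 100))
  tax <- data.frame(
    otu_id = c("o1", "o2", "o3", "o4"),
    lineage = c("Bacteria;Parcubacteria;unclassified",
                "Bacteria;Proteobacteria;Gammaproteobacteria",
                "Bacteria;saccharibacteria;genus_x",   # case-insensitive
                "Bacteria;WS3;unclassified"),
    confidence = c(0.9, 0.95, 0.85, 0.8))
  out <- subset_by_taxa(cnt, tax)
  expect_identical(rownames(out), c("o1", "o3", "o4"))
  expect_identical(rownames(subset_by_taxa(cnt, tax, "Proteobacteria")), "o2")
  expect_error(subset_by_taxa(cnt, tax, "Archaea"), "no OTU matches")
  expect_length(candidate_phyla(), 8L)
})

test_that("filter order matters and the documented order is filter-then-subset", {
  # o1 passes the threshold only on the full table; o2 only matters for
  # the subset. Applying subset first would also keep o1 (total 80), so
  # the two orders differ when thresholds are re-applied after subsetting.
  cnt <- make_counts(c(o1 = 80, o2 = 60, o3 = 100))
  tax <- data.frame(otu_id = c("o1", "o2", "o3"),
                    lineage = c("Bacteria;Parcubacteria;x",
                                "Bacteria;Parcubacteria;y",
                                "Bacteria;Proteobacteria;z"),
                    confidence = rep(0.9, 3))
  filtered_then_subset <- subset_by_taxa(filter_min_count(cnt, 75), tax)
  expect_identical(rownames(filtered_then_subset), "o1")
  subset_then_filtered <- filter_min_count(subset_by_taxa(cnt, tax), 60)
  expect_identical(rownames(subset_then_filtered), c("o1", "o2"))
})

test_that("pairwise turnover: 0 for identical, 1 for disjoint, symmetric", {
  tr <- simulate_tree(6, "star")
  cnt <- matrix(0L, 6, 3, dimnames = list(tr$tip.label, c("s1", "s2", "s3")))
  cnt[1:3, 1] <- c(4L, 2L, 2L)
  cnt[1:3, 2] <- c(8L, 4L, 4L)   # same composition, double depth
  cnt[4:6, 3] <- 5L              # disjoint from both
  tm <- pairwise_turnover(tr, cnt)
  expect_equal(tm["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(tm["s1", "s3"], 1, tolerance = 1e-12)
  expect_equal(unname(diag(tm)), rep(0, 3))
  # property: symmetry, zero diagonal, [0,1] on random instances
  for (seed in 1:10) {
    inst <- random_instance(seed)
    m <- pairwise_turnover(inst$tree, inst$counts)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    expect_true(all(diag(m) == 0))
  }
})

test_that("pairwise turnover matches a two-group partition per pair", {
  inst <- random_instance(17)
  m <- pairwise_turnover(inst$tree, inst$counts)
  s <- colnames(inst$counts)[1:2]
  g2 <- new_grouping(stats::setNames(c("a", "b"), s))
  p <- phylo_partition(inst$tree, inst$counts[, s], g2)
  expect_equal(m[s[1], s[2]], p$turnover, tolerance = 1e-12)
})

test_that("within-group mean turnover averages replicate pairs", {
  tm <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.6,
                 0.5, 0.6, 0), 3, byrow = TRUE,
               dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  g <- new_grouping(c(s1 = "a", s2 = "a", s3 = "b"))
  wg <- within_group_mean_turnover(tm, g)
  expect_equal(wg[["a"]], 0.1)
  expect_true(is.na(wg[["b"]]))   # singleton group: undefined
})

test_that("PCoA recovers planted configurations", {
  # equilateral: 3 points at mutual distance 1
  d3 <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(d3) <- 0
  fit <- pcoa_turnover(d3, n_axes = 2)
  rec <- as.matrix(dist(fit$coordinates))
  expect_lt(max(abs(rec - d3)), 1e-9)

  # planted planar configuration
  xy <- cbind(c(0, 3, 3, 0), c(0, 0, 4, 4))
  rownames(xy) <- paste0("s", 1:4)
  d4 <- as.matrix(dist(xy))
  fit4 <- pcoa_turnover(d4, n_axes = 2)
  expect_lt(max(abs(as.matrix(dist(fit4$coordinates)) - d4)), 1e-9)

  # requesting more axes than the (planar) configuration supports warns
  expect_warning(pcoa_turnover(d4, n_axes = 3), "truncating")

  # duplicate samples land on coincident coordinates
  d5 <- as.matrix(dist(xy[c(1, 1, 2, 3), ]))
  dimnames(d5) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit5 <- pcoa_turnover(d5, n_axes = 2)
  expect_lt(max(abs(fit5$coordinates[1, ] - fit5$coordinates[2, ])), 1e-9)
})

test_that("lineage contributions: root is 1, disjoint cover sums to 1", {
  ds <- generate_dwtp_preset(5)
  p <- phylo_partition(ds$tree, ds$counts, ds$grouping)
  root_label <- p$ba$node_labels[p$ba$bi$root]
  expect_equal(lineage_contribution(p, root_label), 1, tolerance = 1e-9)
  # the three top-level clades partition all branches except the root
  tops <- unlist(ds$truth$clade_nodes)
  fr <- vapply(tops, function(nd) lineage_contribution(p, nd), numeric(1))
  # remaining branches are the three clade stems' parents = root only,
  # so the stems are included in the clades and fractions sum to 1
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(all(fr >= 0))
})

test_that("lineage contribution matches a brute-force subtree sum", {
  inst <- random_instance(23)
  p <- phylo_partition(inst$tree, inst$counts, inst$grouping)
  orc <- oracle_partition(inst$tree, inst$counts, inst$grouping)
  node <- inst$tree$edge[1, 1]  # some internal node
  tips <- ape::extract.clade(inst$tree, node)$tip.label
  ids <- as.integer(names(orc$branch_beta))
  in_clade <- vapply(ids, function(v) {
    vt <- if (v <= length(inst$tree$tip.label)) inst$tree$tip.label[v] else
      ape::extract.clade(inst$tree, v)$tip.label
    all(vt %in% tips)
  }, logical(1))
  expected <- sum(orc$branch_beta[in_clade]) / orc$H_beta
  expect_equal(lineage_contribution(p, node), expected, tolerance = 1e-9)
})

test_that("group lineage proportions report per-group descent shares", {
  ds <- generate_dwtp_preset(6)
  ba <- branch_frequencies(ds$tree, ds$counts, ds$grouping)
  root_label <- ba$node_labels[ba$bi$root]
  expect_equal(unname(group_lineage_proportions(ba, root_label)), rep(1, 3))
  # a leaf private to the gw_exclusive clade has zero share where absent
  sh <- group_lineage_proportions(ba, ds$truth$planted$treated$node)
  expect_true(all(sh >= 0 & sh <= 1))
})

test_that("iTOL export colors the gradient ends and references real nodes", {
  # clade N is shared at identical conditional frequencies (null
  # contribution, must be yellow); C and D are group-exclusive (maximal,
  # dark red at the top)
  tr <- parse_tree("((A:1,B:1)N:1,(C:1,D:1)M:1);")
  g <- new_grouping(c(s1 = "g1", s2 = "g2"))
  cnt <- matrix(c(20L, 20L, 60L, 0L, 10L, 10L, 0L, 30L), 4,
                dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  p <- phylo_partition(tr, cnt, g)
  ann <- export_itol_annotations(tr, p)
  data_lines <- ann$tree_colors[-(1:3)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  cols <- vapply(parts, `[[`, character(1), 3)
  hb <- p$branch_beta
  expect_equal(cols[which.max(hb)], "#8B0000")        # max -> dark red
  expect_true(any(hb == 0))
  expect_true(all(cols[hb == 0] == "#FFFF00"))        # null -> yellow

  # on the preset, every referenced node resolves to nodes of the tree
  ds <- generate_dwtp_preset(3)
  pp <- phylo_partition(ds$tree, ds$counts, ds$grouping)
  ann2 <- export_itol_annotations(ds$tree, pp)
  refs <- vapply(strsplit(ann2$tree_colors[-(1:3)], "\t", fixed = TRUE),
                 `[[`, character(1), 1)
  tips <- unlist(strsplit(refs, "|", fixed = TRUE))
  known <- c(ds$tree$tip.label, ds$tree$node.label)
  expect_true(all(tips %in% known))
  # multibar: one row per leaf, fields per group
  bar_rows <- ann2$multibar[-(1:6)]
  expect_length(bar_rows, length(ds$tree$tip.label))
  d <- file.path(tempdir(), "itol_out")
  export_itol_annotations(ds$tree, pp, dir = d)
  expect_true(file.exists(file.path(d, "itol_branch_contributions.txt")))
})
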