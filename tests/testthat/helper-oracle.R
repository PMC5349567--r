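# Independent first-principles oracle for the entropy partition.
# Deliberately naive: descendant sets by recursion on the edge matrix,
# group pooling and every entropy by explicit loops over branches and
# groups, straight from the definitions. Shares no code path with the
# package's postorder-accumulation implementation.

oracle_partition <- function(tree, counts, grouping, weighting = "equal") {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode

  descendant_tips <- function(v) {
    if (v <= n_tip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, descendant_tips))
  }

  groups <- grouping$groups
  G <- length(groups)
  pooled <- matrix(0, nrow(counts), G, dimnames = list(rownames(counts), groups))
  for (g in seq_len(G)) {
    for (s in colnames(counts)) {
      if (grouping$group[match(s, grouping$sample)] == groups[g]) {
        pooled[, g] <- pooled[, g] + counts[, s]
      }
    }
  }
  totals <- colSums(pooled)
  w <- if (identical(weighting, "equal")) grouping$weights else totals / sum(totals)

  nodes <- setdiff(seq_len(n_node), root)
  L <- vapply(nodes, function(v) tree$edge.length[which(tree$edge[, 2] == v)], numeric(1))
  a <- matrix(0, length(nodes), G)
  for (k in seq_along(nodes)) {
    tips <- tree$tip.label[descendant_tips(nodes[k])]
    for (g in seq_len(G)) {
      a[k, g] <- sum(pooled[rownames(pooled) %in% tips, g]) / totals[g]
    }
  }
  p_ig <- a
  for (g in seq_len(G)) p_ig[, g] <- a[, g] * w[g]
  p_i <- rowSums(p_ig)
  T_bar <- sum(L * p_i)

  H_gamma <- 0
  for (k in seq_along(nodes)) {
    if (p_i[k] > 0) H_gamma <- H_gamma - L[k] / T_bar * p_i[k] * log(p_i[k])
  }
  H_group <- numeric(G)
  for (g in seq_len(G)) {
    for (k in seq_along(nodes)) {
      if (a[k, g] > 0) H_group[g] <- H_group[g] - L[k] / T_bar * a[k, g] * log(a[k, g])
    }
  }
  H_alpha <- sum(w * H_group)
  branch_beta <- numeric(length(nodes))
  for (k in seq_along(nodes)) {
    for (g in seq_len(G)) {
      if (p_ig[k, g] > 0) {
        branch_beta[k] <- branch_beta[k] +
          L[k] / T_bar * p_ig[k, g] * log(p_ig[k, g] / (p_i[k] * w[g]))
      }
    }
  }
  list(H_gamma = H_gamma, H_alpha = H_alpha, H_beta = sum(branch_beta),
       H_group = H_group, T_bar = T_bar,
       branch_beta = stats::setNames(branch_beta, nodes))
}

# Random valid (tree, counts, grouping) instance on <= max_leaves leaves.
random_instance <- function(seed, max_leaves = 8L) {
  set.seed(seed)
  n <- sample(3:max_leaves, 1L)
  tree <- ape::rtree(n)
  G <- sample(2:3, 1L)
  S <- G + sample(0:3, 1L)
  extra <- if (S > G) paste0("g", sample(G, S - G, replace = TRUE)) else character(0)
  grp <- c(paste0("g", seq_len(G)), extra)
  names(grp) <- paste0("s", seq_len(S))
  repeat {
    counts <- matrix(rpois(n * S, lambda = 4), n, S,
                     dimnames = list(tree$tip.label, names(grp)))
    if (all(colSums(counts) > 0)) break
  }
  storage.mode(counts) <- "integer"
  list(tree = tree, counts = counts, grouping = new_grouping(grp))
}

# Star-tree fixture: two equal-weight groups with a planted unshared
# fraction x and the remaining reads on shared leaves at identical
# frequencies. K*x and K*(1-x)/2 must be whole numbers.
unshared_fixture <- function(x, K = 100L) {
  stopifnot(abs(K * x - round(K * x)) < 1e-9)
  tree <- parse_tree("(sh1:1,sh2:1,e1:1,e2:1);")
  shared <- as.integer(round(K * (1 - x) / 2))
  excl <- as.integer(round(K * x))
  counts <- matrix(c(shared, shared, excl, 0L,
                     shared, shared, 0L, excl), 4L,
                   dimnames = list(c("sh1", "sh2", "e1", "e2"), c("s1", "s2")))
  list(tree = tree, counts = counts,
       grouping = new_grouping(c(s1 = "g1", s2 = "g2")))
}
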