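# Internal tree bookkeeping shared by the entropy and lineage code.
# All per-branch quantities are indexed by the postorder edge list; each
# branch is identified with its child node (the root carries no branch).

.branch_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    tree = tree,
    n_tip = n_tip,
    n_node = n_tip + tree$Nnode,
    root = n_tip + 1L,
    edge = po$edge,
    edge_length = if (is.null(po$edge.length)) rep(0, nrow(po$edge)) else po$edge.length
  )
}

# Human-readable lineage identifier per node: tip label for leaves, the
# newick internal label when present, otherwise "L<node number>" (a
# deterministic preorder-derived numbering).
.node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  labs <- character(n_node)
  labs[seq_len(n_tip)] <- tree$tip.label
  internal <- (n_tip + 1L):n_node
  nl <- tree$node.label
  for (v in internal) {
    cand <- if (!is.null(nl)) nl[v - n_tip] else ""
    labs[v] <- if (!is.na(cand) && nzchar(cand)) cand else paste0("L", v)
  }
  labs
}

# Accumulate leaf-level counts up the tree: column-wise postorder sweep.
# leaf_counts is an n_tip x K matrix in tip-number order.
.node_counts <- function(bi, leaf_counts) {
  K <- ncol(leaf_counts)
  C <- matrix(0, bi$n_node, K)
  C[seq_len(bi$n_tip), ] <- leaf_counts
  e <- bi$edge
  for (i in seq_len(nrow(e))) {
    C[e[i, 1L], ] <- C[e[i, 1L], ] + C[e[i, 2L], ]
  }
  C
}

# Map an OTU x K count matrix onto tree tips. OTUs absent from the tree
# are a hard error (their placement is undefined); tips without counts
# are kept at 0 so the tree's branch set (and hence mean depth) is stable.
.leaf_matrix <- function(tree, counts) {
  off <- setdiff(rownames(counts), tree$tip.label)
  if (length(off)) {
    stop("OTU(s) absent from the tree: ", paste(utils::head(off, 10L), collapse = ", "),
         if (length(off) > 10L) ", ..." else "", call. = FALSE)
  }
  m <- matrix(0, length(tree$tip.label), ncol(counts),
              dimnames = list(tree$tip.label, colnames(counts)))
  m[rownames(counts), ] <- counts
  m
}

# Pool sample columns by group, preserving the grouping's group order.
.pool_by_group <- function(counts, grouping) {
  miss <- setdiff(colnames(counts), grouping$sample)
  if (length(miss)) {
    stop("sample(s) missing from grouping: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- grouping$group[match(colnames(counts), grouping$sample)]
  pooled <- vapply(grouping$groups, function(gr) {
    rowSums(counts[, g == gr, drop = FALSE])
  }, numeric(nrow(counts)))
  pooled <- matrix(pooled, nrow = nrow(counts),
                   dimnames = list(rownames(counts), grouping$groups))
  pooled
}

#' Per-branch joint and within-group frequencies
#'
#' Computes, for every branch of a rooted tree, the within-group frequency
#' `a_ig` (reads descending from the branch in group g divided by the
#' total reads of group g, samples pooled within the group), the joint
#' frequency `p_ig = w_g * a_ig`, the marginal `p_i = sum_g p_ig`, and the
#' abundance-weighted mean root-to-observation depth
#' `T_bar = sum_i L_i * p_i`. These are the sufficient statistics for all
#' entropy partitions.
#'
#' With the default `weighting = "equal"` each group receives weight
#' `w_g = 1/G` (or the custom weights stored in the grouping), so groups
#' contribute equally regardless of how many reads they carry;
#' `weighting = "proportional"` restores the unmodified read-proportional
#' estimator for comparison.
#'
#' @param tree A rooted `phylo` tree (see [parse_tree()]).
#' @param counts OTU x sample integer matrix (see [parse_count_table()]),
#'   or an already pooled OTU x group matrix whose columns match the
#'   grouping's groups.
#' @param grouping A `grouping` object (see [parse_grouping()]).
#' @param weighting `"equal"` (group weights from the grouping, default
#'   `1/G`) or `"proportional"` (weights proportional to group read totals).
#' @return An object of class `branch_abundance` with components `node`
#'   (child node id per branch), `label`, `L` (branch lengths), `a`, `p_ig`
#'   (branch x group matrices), `p_i`, `T_bar`, `weights`, `groups`,
#'   `group_totals`, and the tree.
#' @export
branch_frequencies <- function(tree, counts, grouping,
                               weighting = c("equal", "proportional")) {
  weighting <- match.arg(weighting)
  tree <- validate_tree(tree)
  if (identical(colnames(counts), grouping$groups)) {
    pooled <- counts
  } else {
    pooled <- .pool_by_group(counts, grouping)
  }
  totals <- colSums(pooled)
  if (any(totals <= 0)) {
    stop("group(s) with zero reads: ",
         paste(grouping$groups[totals <= 0], collapse = ", "), call. = FALSE)
  }
  w <- if (weighting == "equal") grouping$weights else totals / sum(totals)
  bi <- .branch_index(tree)
  C <- .node_counts(bi, .leaf_matrix(tree, pooled))
  child <- bi$edge[, 2L]
  labels <- .node_labels(tree)
  a <- sweep(C[child, , drop = FALSE], 2L, totals, "/")
  dimnames(a) <- list(labels[child], grouping$groups)
  p_ig <- sweep(a, 2L, w, "*")
  p_i <- rowSums(p_ig)
  structure(
    list(
      node = child,
      parent = bi$edge[, 1L],
      label = labels[child],
      L = bi$edge_length,
      a = a,
      p_ig = p_ig,
      p_i = p_i,
      T_bar = sum(bi$edge_length * p_i),
      weights = stats::setNames(as.numeric(w), grouping$groups),
      groups = grouping$groups,
      group_totals = stats::setNames(as.numeric(totals), grouping$groups),
      node_labels = labels,
      bi = bi
    ),
    class = "branch_abundance"
  )
}

#' @export
print.branch_abundance <- function(x, ...) {
  cat("branch_abundance:", length(x$L), "branches,", length(x$groups),
      "groups, T_bar =", format(x$T_bar), "\n")
  invisible(x)
}
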