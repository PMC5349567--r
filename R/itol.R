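# iTOL annotation export: a branch-color gradient over the per-branch
# beta contributions (yellow = no contribution, dark red = maximum) and a
# per-leaf multibar of per-group read counts.

# linear yellow -> dark red ramp on [0, 1]
.itol_gradient <- function(x) {
  ramp <- grDevices::colorRamp(c("#FFFF00", "#8B0000"))
  rgb <- ramp(pmin(pmax(x, 0), 1))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

# iTOL addresses internal nodes by label or by a pair of descendant tips.
.itol_node_ref <- function(ba, node) {
  if (node <= ba$bi$n_tip) return(ba$node_labels[node])
  tips <- .lineage_nodes(ba, node)
  tips <- tips[tips <= ba$bi$n_tip]
  if (length(tips) >= 2L) {
    paste(ba$node_labels[c(min(tips), max(tips))], collapse = "|")
  } else {
    ba$node_labels[node]
  }
}

#' Export iTOL annotation datasets
#'
#' Builds two plain-text iTOL datasets from a diversity partition: a
#' `TREE_COLORS` file coloring every branch by its beta contribution on
#' a yellow-to-dark-red gradient (yellow = null contribution, dark red =
#' the maximum observed), and a `DATASET_MULTIBAR` file showing each
#' leaf's per-group read counts as multi-value bars.
#'
#' @param tree The tree the partition was computed on.
#' @param partition A `phylo_partition`.
#' @param counts OTU x sample count matrix used for the per-leaf bars
#'   (pooled by group via `grouping`); defaults to the partition's pooled
#'   group frequencies scaled by group totals.
#' @param grouping Optional `grouping` to pool `counts`; unused when
#'   `counts` is already per group.
#' @param dir Optional directory; when given, writes
#'   `itol_branch_contributions.txt` and `itol_group_multibar.txt`.
#' @return Invisibly (when writing) or visibly a list of two character
#'   vectors: `tree_colors` and `multibar`, each a full iTOL dataset.
#' @export
export_itol_annotations <- function(tree, partition, counts = NULL,
                                    grouping = NULL, dir = NULL) {
  stopifnot(inherits(partition, "phylo_partition"))
  ba <- partition$ba
  hb <- partition$branch_beta
  if (is.null(hb)) stop("partition has no beta contributions (single group?)", call. = FALSE)
  top <- max(hb)
  scaled <- if (top > 0) hb / top else rep(0, length(hb))
  cols <- .itol_gradient(scaled)
  refs <- vapply(ba$node, function(v) .itol_node_ref(ba, v), character(1))
  tree_colors <- c(
    "TREE_COLORS",
    "SEPARATOR TAB",
    "DATA",
    paste(refs, "branch", cols, "normal", sep = "\t")
  )

  if (is.null(counts)) {
    leaf_counts <- sweep(ba$a[ba$node <= ba$bi$n_tip, , drop = FALSE],
                         2L, ba$group_totals, "*")
    rownames(leaf_counts) <- ba$label[ba$node <= ba$bi$n_tip]
  } else {
    leaf_counts <- if (!is.null(grouping)) .pool_by_group(counts, grouping) else counts
  }
  groups <- colnames(leaf_counts)
  palette <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")[seq_along(groups)]
  multibar <- c(
    "DATASET_MULTIBAR",
    "SEPARATOR TAB",
    "DATASET_LABEL\tper-group read counts",
    paste0("FIELD_COLORS\t", paste(palette, collapse = "\t")),
    paste0("FIELD_LABELS\t", paste(groups, collapse = "\t")),
    "DATA",
    vapply(seq_len(nrow(leaf_counts)), function(i) {
      paste(c(rownames(leaf_counts)[i], leaf_counts[i, ]), collapse = "\t")
    }, character(1))
  )

  out <- list(tree_colors = tree_colors, multibar = multibar)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(tree_colors, file.path(dir, "itol_branch_contributions.txt"))
    writeLines(multibar, file.path(dir, "itol_group_multibar.txt"))
    return(invisible(out))
  }
  out
}
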