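# Downstream community procedures: OTU filters, candidate-phyla
# subsetting, pairwise turnover distances, PCoA, and lineage reports.

#' Discard low-count OTUs
#'
#' Removes OTUs whose total read count across all samples falls below
#' `threshold`. The default of 75 reflects the common practice of
#' dropping OTU clusters supported by fewer than 75 sequences.
#'
#' @param counts OTU x sample integer matrix.
#' @param threshold Minimum total count an OTU must reach to be kept.
#' @return The filtered count matrix.
#' @export
filter_min_count <- function(counts, threshold = 75L) {
  stopifnot(is.matrix(counts), threshold >= 0)
  keep <- rowSums(counts) >= threshold
  if (!any(keep)) stop("all OTUs fall below the count threshold", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Candidate phyla / Candidate Phyla Radiation target names
#'
#' The eight candidate phyla and CPR superphyla commonly targeted when
#' isolating the "microbial dark matter" fraction of 16S surveys:
#' Parcubacteria (OD1), Microgenomates (OP11), Saccharibacteria (TM7),
#' Dependentiae (TM6), OP3, OP1, BRC1, and WS3. Shipped as a plain-text
#' config in `inst/extdata/candidate_phyla.txt`.
#'
#' @return Character vector of taxon names.
#' @export
candidate_phyla <- function() {
  path <- system.file("extdata", "candidate_phyla.txt", package = "phylopart")
  if (nzchar(path)) {
    x <- readLines(path, warn = FALSE)
    x <- trimws(x[!grepl("^\\s*#", x)])
    return(x[nzchar(x)])
  }
  c("Parcubacteria", "Microgenomates", "Saccharibacteria", "Dependentiae",
    "OP3", "OP1", "BRC1", "WS3")
}

#' Subset a count table to OTUs matching target taxa
#'
#' Keeps OTUs whose lineage string contains any of the target taxa,
#' matched case-insensitively as substrings of the individual rank names
#' (lineages are split on `;`). The default target list is the eight
#' candidate phyla of [candidate_phyla()].
#'
#' @param counts OTU x sample integer matrix.
#' @param taxonomy Data.frame from [parse_taxonomy()].
#' @param target_taxa Character vector of taxon names to retain.
#' @return The subset count matrix.
#' @export
subset_by_taxa <- function(counts, taxonomy, target_taxa = candidate_phyla()) {
  stopifnot(is.matrix(counts), length(target_taxa) >= 1L)
  lin <- taxonomy$lineage[match(rownames(counts), taxonomy$otu_id)]
  if (anyNA(lin)) {
    stop("OTU(s) missing from taxonomy: ",
         paste(rownames(counts)[is.na(lin)], collapse = ", "), call. = FALSE)
  }
  targets <- tolower(target_taxa)
  hit <- vapply(lin, function(s) {
    ranks <- tolower(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    any(vapply(targets, function(t) any(grepl(t, ranks, fixed = TRUE)), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(hit)) {
    stop("no OTU matches the target taxa: ", paste(target_taxa, collapse = ", "),
         call. = FALSE)
  }
  counts[hit, , drop = FALSE]
}

#' Pairwise turnover distance matrix
#'
#' For every pair of samples, the turnover of the two-group partition in
#' which each sample is its own group with weight 1/2. With equal
#' weights the entries do not depend on per-sample sequencing depth. The
#' result is a symmetric matrix with zero diagonal and entries in
#' `[0, 1]`, usable as a distance for ordination.
#'
#' @param tree A rooted `phylo` tree.
#' @param counts OTU x sample integer matrix; every sample must have
#'   reads.
#' @return Object of class `dist`-compatible symmetric matrix
#'   (`turnover_matrix`) with sample dimnames.
#' @export
pairwise_turnover <- function(tree, counts) {
  tree <- validate_tree(tree)
  if (ncol(counts) < 2L) stop("need at least two samples", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("sample(s) with zero reads: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  bi <- .branch_index(tree)
  C <- .node_counts(bi, .leaf_matrix(tree, counts))
  child <- bi$edge[, 2L]
  L <- bi$edge_length
  A <- sweep(C[child, , drop = FALSE], 2L, totals, "/")  # per-sample a_is
  S <- ncol(counts)
  M <- matrix(0, S, S, dimnames = list(colnames(counts), colnames(counts)))
  for (s in seq_len(S - 1L)) {
    for (t in (s + 1L):S) {
      a1 <- A[, s]; a2 <- A[, t]
      p <- (a1 + a2) / 2
      T_bar <- sum(L * p)
      hb <- sum(L * (.plogpq(a1 / 2, p / 2) + .plogpq(a2 / 2, p / 2))) / T_bar
      M[s, t] <- M[t, s] <- hb / log(2)
    }
  }
  structure(M, class = c("turnover_matrix", "matrix"))
}

#' Mean turnover among samples of the same group
#'
#' Averages the off-diagonal turnover entries within each group; a
#' measure of replicate consistency. Groups with a single sample have no
#' within-group pair and report `NA`.
#'
#' @param matrix A symmetric turnover matrix from [pairwise_turnover()].
#' @param grouping A `grouping` covering the matrix's samples.
#' @return Named numeric vector, one mean per group.
#' @export
within_group_mean_turnover <- function(matrix, grouping) {
  ids <- rownames(matrix)
  g <- grouping$group[match(ids, grouping$sample)]
  if (anyNA(g)) stop("sample(s) missing from grouping", call. = FALSE)
  out <- vapply(grouping$groups, function(gr) {
    idx <- which(g == gr)
    if (length(idx) < 2L) return(NA_real_)
    sub <- matrix[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  stats::setNames(out, grouping$groups)
}

#' Principal coordinates analysis of a turnover matrix
#'
#' Classical metric scaling (square the distances, double-center, keep
#' the top positive eigenvalues). Turnover is not guaranteed to be
#' Euclidean-embeddable; negative eigenvalues are dropped and their
#' inertia share is reported. If fewer positive axes exist than
#' requested, the result is truncated with a warning.
#'
#' @param matrix Symmetric distance (turnover) matrix.
#' @param n_axes Number of coordinate axes to return (default 3).
#' @return List with `coordinates` (samples x axes), `eigenvalues`,
#'   `explained` (fraction of positive inertia per kept axis), and
#'   `negative_inertia` (|sum of negative eigenvalues| / sum |all|).
#' @export
pcoa_turnover <- function(matrix, n_axes = 3L) {
  stopifnot(n_axes >= 1L)
  d <- stats::as.dist(matrix)
  # cmdscale warns about non-positive eigenvalues; we handle them
  # explicitly (drop + report negative inertia)
  fit <- suppressWarnings(stats::cmdscale(d, k = attr(d, "Size") - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-12)
  if (length(pos) == 0L) stop("no positive eigenvalue; degenerate configuration", call. = FALSE)
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning("only ", k, " positive axes available; truncating from ", n_axes)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  list(
    coordinates = coords,
    eigenvalues = eig,
    explained = eig[seq_len(k)] / sum(eig[pos]),
    negative_inertia = sum(abs(eig[eig < 0])) / sum(abs(eig))
  )
}

# Resolve a lineage reference (internal node label, "L<number>", or node
# id) to a node number of the tree.
.resolve_node <- function(ba, lineage) {
  labels <- ba$node_labels
  if (is.numeric(lineage)) {
    v <- as.integer(lineage)
    if (v < 1L || v > length(labels)) stop("node id out of range: ", lineage, call. = FALSE)
    return(v)
  }
  v <- which(labels == lineage)
  if (length(v) == 1L) return(v)
  if (length(v) > 1L) stop("ambiguous lineage label: ", lineage, call. = FALSE)
  stop("lineage not found: ", lineage, call. = FALSE)
}

# Node numbers of a lineage: the node itself plus all descendants.
.lineage_nodes <- function(ba, node) {
  e <- ba$bi$edge
  keep <- logical(ba$bi$n_node)
  keep[node] <- TRUE
  # edges are postorder (children before parents); walk in reverse so a
  # flagged parent propagates to its subtree
  for (i in rev(seq_len(nrow(e)))) {
    if (keep[e[i, 1L]]) keep[e[i, 2L]] <- TRUE
  }
  which(keep)
}

#' Share of beta diversity explained by a lineage
#'
#' Sums the per-branch mutual-information contributions over a lineage's
#' subtending branch and every branch inside it, divided by total
#' `H_beta`. The whole tree (root) yields 1; a lineage whose conditional
#' frequencies are identical across groups yields 0.
#'
#' @param partition A `phylo_partition`.
#' @param lineage Internal node label (e.g. `"L42"`), tip label, or node
#'   number.
#' @return Fraction of `H_beta` in `[0, 1]` (up to rounding).
#' @export
lineage_contribution <- function(partition, lineage) {
  stopifnot(inherits(partition, "phylo_partition"))
  if (is.na(partition$H_beta) || partition$H_beta <= 0) {
    stop("H_beta is zero; lineage contributions undefined", call. = FALSE)
  }
  ba <- partition$ba
  nodes <- .lineage_nodes(ba, .resolve_node(ba, lineage))
  sum(partition$branch_beta[ba$node %in% nodes]) / partition$H_beta
}

#' Per-group observation share of a lineage
#'
#' For each group, the fraction of that group's reads descending from
#' the lineage's node (`a_ig` of its subtending branch). The root gives
#' 1 for every group; a lineage absent from a group gives 0.
#'
#' @param ba A `branch_abundance` (or a `phylo_partition`, whose
#'   abundances are used).
#' @param lineage Node label, tip label, or node number.
#' @return Named numeric vector, one share per group.
#' @export
group_lineage_proportions <- function(ba, lineage) {
  if (inherits(ba, "phylo_partition")) ba <- ba$ba
  stopifnot(inherits(ba, "branch_abundance"))
  node <- .resolve_node(ba, lineage)
  if (node == ba$bi$root) {
    return(stats::setNames(rep(1, length(ba$groups)), ba$groups))
  }
  idx <- which(ba$node == node)
  stats::setNames(ba$a[idx, ], ba$groups)
}

#' Write a turnover matrix as TSV
#' @param matrix A turnover (or any labelled symmetric) matrix.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_turnover_matrix <- function(matrix, file) {
  df <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
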