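# Phylogenetic Shannon entropy and its gamma/alpha/beta partition.
#
# All entropies are in nats and depth-normalized by T_bar, the
# abundance-weighted mean root-to-observation path length, so that a star
# tree of n equally abundant leaves has exp(H) = n exactly. The convention
# 0 * ln 0 = 0 applies throughout; branches with zero marginal frequency
# are skipped.

.xlogx <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

# p * log(p / q) with 0 * log(0/q) = 0; q must be positive wherever p is.
.plogpq <- function(p, q) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos] / q[pos])
  out
}

#' Gamma phylogenetic entropy and diversity
#'
#' Pooled-community phylogenetic Shannon entropy
#' `H_gamma = -sum_i (L_i / T_bar) * p_i * ln p_i` and its exponential
#' `D_gamma = exp(H_gamma)`, the equivalent number of equi-abundant
#' independent lineages: the number of branches of a star tree with
#' equally abundant tips that would show the same diversity.
#'
#' @param ba A `branch_abundance` object from [branch_frequencies()].
#' @return List with `H_gamma` (nats) and `D_gamma`.
#' @export
gamma_entropy <- function(ba) {
  stopifnot(inherits(ba, "branch_abundance"))
  if (!(ba$T_bar > 0)) stop("mean depth T_bar is zero; tree has no abundance-weighted branch length", call. = FALSE)
  H <- -sum(ba$L / ba$T_bar * .xlogx(ba$p_i))
  list(H_gamma = H, D_gamma = exp(H))
}

#' Alpha phylogenetic entropy and diversity
#'
#' Per-group phylogenetic entropies
#' `Hp(g) = -sum_i (L_i / T_bar) * a_ig * ln a_ig`, evaluated with the
#' pooled `T_bar` so the partition stays additive, then averaged with the
#' group weights: `H_alpha = sum_g w_g * Hp(g)`. Per-group diversities
#' `D_g = exp(Hp(g))` are the equivalent-lineage counts of each group.
#'
#' @inheritParams gamma_entropy
#' @return List with `H_alpha`, `D_alpha = exp(H_alpha)`, and named
#'   vectors `H_group`, `D_group`.
#' @export
alpha_entropy <- function(ba) {
  stopifnot(inherits(ba, "branch_abundance"))
  if (!(ba$T_bar > 0)) stop("mean depth T_bar is zero", call. = FALSE)
  H_g <- -colSums(ba$L / ba$T_bar * apply(ba$a, 2L, .xlogx))
  H_g <- stats::setNames(as.numeric(H_g), ba$groups)
  H_alpha <- sum(ba$weights * H_g)
  list(H_alpha = H_alpha, D_alpha = exp(H_alpha),
       H_group = H_g, D_group = exp(H_g))
}

#' Beta diversity as phylogenetic mutual information
#'
#' The mutual information between an observation's lineage (the branches
#' on its root-to-tip path) and its group label, decomposed by branch:
#' `H_beta_i = (L_i / T_bar) * sum_g p_ig * ln(p_ig / (p_i * w_g))` and
#' `H_beta = sum_i H_beta_i`. Each branch term is a scaled
#' Kullback-Leibler divergence and therefore nonnegative; `H_beta` is zero
#' iff all groups share identical branch-frequency profiles. The identity
#' `H_gamma = H_alpha + H_beta` holds exactly.
#'
#' @inheritParams gamma_entropy
#' @return List with `H_beta` and the per-branch contribution vector
#'   `branch_beta` (named by lineage label, same order as `ba$L`).
#' @export
beta_mutual_information <- function(ba) {
  stopifnot(inherits(ba, "branch_abundance"))
  if (length(ba$groups) < 2L) stop("beta diversity undefined for a single group", call. = FALSE)
  if (!(ba$T_bar > 0)) stop("mean depth T_bar is zero", call. = FALSE)
  G <- length(ba$groups)
  ref <- ba$p_i %o% ba$weights          # p_i * w_g, the independence baseline
  terms <- .plogpq(ba$p_ig, ref)
  dim(terms) <- c(length(ba$p_i), G)
  hb_i <- ba$L / ba$T_bar * rowSums(terms)
  list(H_beta = sum(hb_i),
       branch_beta = stats::setNames(hb_i, ba$label))
}

#' Entropy of the grouping
#'
#' `H(G) = -sum_g w_g * ln w_g`, the maximum value the phylogenetic
#' mutual information can reach for a fixed design, and hence the
#' normalizer of [turnover()]. Equals `ln G` for equal weights.
#'
#' @param grouping A `grouping` object, or a `branch_abundance` (whose
#'   effective weights are then used).
#' @return Entropy in nats.
#' @export
grouping_entropy <- function(grouping) {
  -sum(.xlogx(grouping$weights))
}

#' Turnover: normalized beta diversity
#'
#' `H_beta / H(G)`, in `[0, 1]`. With two equal-weight groups this is the
#' fraction of observations sitting on lineages not shared between the
#' groups: 0 for identical communities, 1 for fully disjoint ones.
#'
#' @param H_beta Beta mutual information in nats (or a `phylo_partition`,
#'   whose `H_beta` is used).
#' @param grouping A `grouping` or `branch_abundance` supplying the
#'   weights.
#' @return Turnover in `[0, 1]`.
#' @export
turnover <- function(H_beta, grouping) {
  if (inherits(H_beta, "phylo_partition")) H_beta <- H_beta$H_beta
  HG <- grouping_entropy(grouping)
  if (!(HG > 0)) stop("H(G) = 0: turnover undefined for a single group", call. = FALSE)
  H_beta / HG
}

#' Full gamma/alpha/beta diversity partition
#'
#' One-call wrapper: computes branch frequencies and the complete
#' partition with per-branch beta contributions and turnover. The result
#' is deterministic and invariant to the order of sample columns.
#'
#' @inheritParams branch_frequencies
#' @return An object of class `phylo_partition` with fields `H_gamma`,
#'   `H_alpha`, `H_beta`, `D_gamma`, `D_alpha`, `H_group`, `D_group`,
#'   `branch_beta`, `turnover`, `H_G`, `T_bar`, `n_branches`, and the
#'   underlying `branch_abundance` in `$ba`.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' cnt <- matrix(c(10L, 10L, 0L, 0L, 0L, 0L, 10L, 10L), 4,
#'               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
#' grp <- new_grouping(c(s1 = "g1", s2 = "g2"))
#' phylo_partition(tr, cnt, grp)
#' @export
phylo_partition <- function(tree, counts, grouping,
                            weighting = c("equal", "proportional")) {
  ba <- branch_frequencies(tree, counts, grouping, match.arg(weighting))
  gam <- gamma_entropy(ba)
  alp <- alpha_entropy(ba)
  bet <- if (length(ba$groups) >= 2L) beta_mutual_information(ba) else
    list(H_beta = NA_real_, branch_beta = NULL)
  HG <- grouping_entropy(ba)
  structure(
    list(
      H_gamma = gam$H_gamma, D_gamma = gam$D_gamma,
      H_alpha = alp$H_alpha, D_alpha = alp$D_alpha,
      H_group = alp$H_group, D_group = alp$D_group,
      H_beta = bet$H_beta, D_beta = exp(bet$H_beta),
      branch_beta = bet$branch_beta,
      turnover = if (HG > 0 && !is.na(bet$H_beta)) bet$H_beta / HG else NA_real_,
      H_G = HG,
      T_bar = ba$T_bar,
      n_branches = length(ba$L),
      ba = ba
    ),
    class = "phylo_partition"
  )
}

#' @export
print.phylo_partition <- function(x, ...) {
  cat("Phylogenetic diversity partition\n")
  cat(sprintf("  H_gamma = %.6f  D_gamma = %.4f equivalent lineages\n", x$H_gamma, x$D_gamma))
  cat(sprintf("  H_alpha = %.6f  D_alpha = %.4f\n", x$H_alpha, x$D_alpha))
  for (g in names(x$D_group)) {
    cat(sprintf("    %s: D = %.4f\n", g, x$D_group[[g]]))
  }
  if (!is.na(x$H_beta)) {
    cat(sprintf("  H_beta  = %.6f  (mutual information, max H(G) = %.6f)\n", x$H_beta, x$H_G))
    cat(sprintf("  turnover = %.4f\n", x$turnover))
  }
  invisible(x)
}

#' Per-branch table of a diversity partition
#'
#' One row per branch: child node id, lineage label, branch length,
#' marginal and per-group joint frequencies, the branch's beta
#' contribution and its share of total beta.
#'
#' @param partition A `phylo_partition`.
#' @return A data.frame, branches in postorder.
#' @export
branch_table <- function(partition) {
  stopifnot(inherits(partition, "phylo_partition"))
  ba <- partition$ba
  df <- data.frame(
    node_id = ba$node,
    lineage_label = ba$label,
    L_i = ba$L,
    p_i = ba$p_i,
    stringsAsFactors = FALSE
  )
  for (g in ba$groups) df[[paste0("p_", g)]] <- ba$p_ig[, g]
  if (!is.null(partition$branch_beta)) {
    df$H_beta_i <- unname(partition$branch_beta)
    df$contribution_fraction <- if (partition$H_beta > 0)
      unname(partition$branch_beta) / partition$H_beta else 0
  }
  df
}

#' Write the partition summary (JSON) and branch table (TSV)
#'
#' @param partition A `phylo_partition`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "phylo_partition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir, "partition_summary.json")
  table_path <- file.path(dir, "branch_table.tsv")
  s <- list(
    H_gamma = partition$H_gamma, H_alpha = partition$H_alpha,
    H_beta = partition$H_beta, D_gamma = partition$D_gamma,
    D_alpha = partition$D_alpha, D_beta = partition$D_beta,
    per_group_D = as.list(partition$D_group),
    turnover = partition$turnover, H_G = partition$H_G,
    n_branches = partition$n_branches, T_bar = partition$T_bar
  )
  jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(branch_table(partition), table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(summary_path, table_path))
}
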