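# Permutation test of beta diversity.
#
# The null hypothesis is exchangeability of group labels across
# observations (individual reads). A permutation re-assigns every read a
# group label drawn without replacement from the pooled label multiset,
# preserving each group's read total exactly; conditional on the margins
# this is a multivariate hypergeometric split of each OTU's pooled count,
# sampled with stats::r2dtable (Patefield's algorithm).

#' Randomly re-assign group labels to observations
#'
#' One draw of the permutation null: pools each OTU's reads across
#' groups and splits them back so that the original per-group read totals
#' are preserved exactly and every assignment of labels to reads is
#' equally likely.
#'
#' @inheritParams branch_frequencies
#' @param seed Optional integer seed for reproducibility.
#' @return OTU x group integer matrix of permuted group-level counts.
#' @export
permute_observation_labels <- function(counts, grouping, seed = NULL) {
  if (length(grouping$groups) < 2L) stop("permutation needs at least two groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pooled <- if (identical(colnames(counts), grouping$groups)) counts else
    .pool_by_group(counts, grouping)
  totals <- colSums(pooled)
  tab <- stats::r2dtable(1L, rowSums(pooled), totals)[[1L]]
  dimnames(tab) <- dimnames(pooled)
  tab
}

# Batched H_beta over many group-level tables sharing margins. Tables are
# stacked column-wise (G columns per table) so one postorder sweep and a
# handful of matrix ops score every permutation.
.beta_batch <- function(bi, leaf_counts_wide, G, B, totals, w) {
  C <- .node_counts(bi, leaf_counts_wide)
  child <- bi$edge[, 2L]
  L <- bi$edge_length
  A <- sweep(C[child, , drop = FALSE], 2L, rep(totals, B), "/")
  P <- sweep(A, 2L, rep(w, B), "*")
  E <- length(child)
  p_i <- matrix(0, E, B)
  for (g in seq_len(G)) p_i <- p_i + P[, seq(g, G * B, by = G), drop = FALSE]
  terms <- matrix(0, E, B)
  for (g in seq_len(G)) {
    Pg <- P[, seq(g, G * B, by = G), drop = FALSE]
    terms <- terms + .plogpq(Pg, p_i * w[g])
  }
  dim(terms) <- c(E, B)
  T_bar <- colSums(L * p_i)
  colSums(L * terms) / T_bar
}

#' Permutation test of phylogenetic beta diversity
#'
#' Tests whether the observed mutual information between lineage and
#' grouping exceeds what label exchangeability alone produces. Each
#' permutation re-assigns group labels to individual reads (default) or
#' to whole samples, preserving per-group totals, and the full statistic
#' -- including the equal-group weighting -- is recomputed. The test is
#' one-sided (H_beta >= 0 by construction) and uses the add-one
#' Monte Carlo estimator, so the smallest attainable p-value is
#' `1 / (n_permutations + 1)`.
#'
#' @inheritParams branch_frequencies
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed; stored in the result.
#' @param unit `"read"` (permute individual reads, default) or
#'   `"sample"` (permute whole samples across groups, for sensitivity
#'   analysis; requires more samples than groups).
#' @return An object of class `permutation_result`: `H_beta_obs`,
#'   `p_value`, `null` (vector of permuted H_beta), `null_mean`,
#'   `null_sd`, `null_quantiles`, `n_permutations`, `unit`, `seed`.
#' @export
permutation_test <- function(tree, counts, grouping, n_permutations = 999L,
                             seed = NULL, unit = c("read", "sample"),
                             weighting = c("equal", "proportional")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  if (!is.numeric(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  if (length(grouping$groups) < 2L) stop("permutation needs at least two groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  tree <- validate_tree(tree)
  ba <- branch_frequencies(tree, counts, grouping, weighting)
  obs <- beta_mutual_information(ba)$H_beta

  G <- length(ba$groups)
  totals <- ba$group_totals
  w <- ba$weights
  bi <- ba$bi

  if (unit == "read") {
    pooled <- if (identical(colnames(counts), ba$groups)) counts else
      .pool_by_group(counts, grouping)
    otu_pool <- rowSums(pooled)
    tip_row <- match(rownames(pooled), tree$tip.label)
    n_tip <- bi$n_tip
    # chunk the permutations so the stacked matrix stays small
    chunk <- max(1L, min(n_permutations, floor(5e6 / (bi$n_node * G))))
    null <- numeric(n_permutations)
    done <- 0L
    while (done < n_permutations) {
      B <- min(chunk, n_permutations - done)
      tabs <- stats::r2dtable(B, otu_pool, totals)
      wide <- matrix(0, n_tip, G * B)
      for (b in seq_len(B)) {
        wide[tip_row, (b - 1L) * G + seq_len(G)] <- tabs[[b]]
      }
      null[done + seq_len(B)] <- .beta_batch(bi, wide, G, B, totals, w)
      done <- done + B
    }
  } else {
    ns <- length(grouping$sample)
    if (ns <= length(grouping$groups)) {
      stop("sample-level permutation needs more samples than groups", call. = FALSE)
    }
    null <- vapply(seq_len(n_permutations), function(b) {
      perm <- new_grouping(
        stats::setNames(sample(grouping$group), grouping$sample),
        weights = "equal"
      )
      ba_p <- branch_frequencies(tree, counts, perm, weighting)
      beta_mutual_information(ba_p)$H_beta
    }, numeric(1))
  }

  p <- (1 + sum(null >= obs)) / (1 + n_permutations)
  structure(
    list(
      H_beta_obs = obs,
      p_value = p,
      null = null,
      null_mean = mean(null),
      null_sd = stats::sd(null),
      null_quantiles = stats::quantile(null, c(0.5, 0.9, 0.95, 0.99)),
      n_permutations = n_permutations,
      unit = unit,
      seed = seed
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test of phylogenetic beta diversity (", x$unit, "-level)\n", sep = "")
  cat(sprintf("  observed H_beta = %.6f\n", x$H_beta_obs))
  cat(sprintf("  null mean %.6f, sd %.6f (%d permutations)\n",
              x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  p-value = %.4g\n", x$p_value))
  if (!is.null(x$seed)) cat("  seed =", x$seed, "\n")
  invisible(x)
}
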