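# Synthetic community generator. Plants a known clade-by-group share
# structure on a simulated tree and draws multinomial reads, so every
# stage of the pipeline can be exercised against a known ground truth.

#' Simulate a rooted tree
#'
#' `model = "star"`: all leaves attached to the root with unit branch
#' lengths (the reference geometry for which exp(H) equals the leaf count
#' under equal abundance). `model = "yule"`: a pure-birth tree with
#' exponential waiting times (via [ape::rphylo()] with zero death rate).
#' Internal nodes are labelled `L<node number>`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param model `"star"` or `"yule"`.
#' @param seed Optional integer seed; the same seed reproduces the tree.
#' @param tip_prefix Prefix for generated leaf names.
#' @return A rooted `phylo` with branch lengths and node labels.
#' @export
simulate_tree <- function(n_leaves, model = c("star", "yule"), seed = NULL,
                          tip_prefix = "otu") {
  model <- match.arg(model)
  if (n_leaves < 2L) stop("n_leaves must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (model == "star") {
    tree <- ape::stree(n_leaves, type = "star")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree <- ape::rphylo(n_leaves, birth = 1, death = 0)
  }
  tree$tip.label <- paste0(tip_prefix, seq_len(n_leaves))
  tree$node.label <- paste0("L", n_leaves + seq_len(tree$Nnode))
  validate_tree(tree)
}

#' Define a synthetic community scenario
#'
#' A scenario plants named clades with per-group expected observation
#' shares; whatever share remains in each group goes to a common
#' "shared" leaf pool with identical within-pool frequencies across
#' groups, so the expected between-group signal comes only from the
#' planted shares. Within-clade leaf frequencies are identical across
#' groups (optionally log-normal rather than uniform), which keeps the
#' expected turnover analytically tractable.
#'
#' @param groups Character vector of group names.
#' @param clades Named list: each element `list(n_leaves =, shares =)`
#'   where `shares` is a numeric vector (one value per group, in group
#'   order) of expected observation shares.
#' @param shared_leaves Number of leaves in the shared pool.
#' @param tree_model `"star"` (flat tree, unit branches; clades are leaf
#'   sets) or `"yule"` (each clade a depth-normalized pure-birth subtree
#'   on a stem of length 1).
#' @param samples_per_group Replicate samples per group (scalar or named
#'   per group).
#' @param depth Reads per sample (scalar or named per group).
#' @param within_clade_sd Log-sd of within-clade leaf weights; 0 gives
#'   equal frequencies within each clade.
#' @param overdispersion Optional Dirichlet concentration; finite values
#'   add per-sample compositional noise (smaller = noisier). `NULL`
#'   (default) draws plain multinomial reads.
#' @param seed Integer seed used for tree simulation, leaf weights and
#'   read sampling.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(groups, clades, shared_leaves = 0L,
                               tree_model = c("star", "yule"),
                               samples_per_group = 1L, depth = 1000L,
                               within_clade_sd = 0, overdispersion = NULL,
                               seed = NULL) {
  tree_model <- match.arg(tree_model)
  G <- length(groups)
  stopifnot(G >= 1L, length(clades) >= 1L)
  if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
    stop("clades must be named", call. = FALSE)
  }
  share_mat <- vapply(clades, function(cl) {
    stopifnot(is.numeric(cl$shares), length(cl$shares) == G, cl$n_leaves >= 1L)
    if (any(cl$shares < 0)) stop("negative clade share", call. = FALSE)
    cl$shares
  }, numeric(G))
  share_mat <- matrix(share_mat, nrow = G,
                      dimnames = list(groups, names(clades)))
  shared_share <- 1 - rowSums(share_mat)
  if (any(shared_share < -1e-9)) {
    stop("clade shares exceed 1 for group(s): ",
         paste(groups[shared_share < -1e-9], collapse = ", "), call. = FALSE)
  }
  shared_share <- pmax(shared_share, 0)
  if (any(shared_share > 0) && shared_leaves < 1L) {
    stop("shares leave a shared remainder but shared_leaves = 0", call. = FALSE)
  }
  sp <- if (length(samples_per_group) == 1L)
    stats::setNames(rep(as.integer(samples_per_group), G), groups) else samples_per_group[groups]
  dp <- if (length(depth) == 1L)
    stats::setNames(rep(as.integer(depth), G), groups) else depth[groups]
  if (any(dp < 1L)) stop("depth must be >= 1", call. = FALSE)
  structure(
    list(groups = groups, clades = clades, clade_shares = share_mat,
         shared_share = stats::setNames(shared_share, groups),
         shared_leaves = as.integer(shared_leaves), tree_model = tree_model,
         samples_per_group = sp, depth = dp,
         within_clade_sd = within_clade_sd, overdispersion = overdispersion,
         seed = seed),
    class = "synthetic_scenario"
  )
}

# Leaf names per clade (shared pool last), fixing the leaf order used by
# both the tree and the profiles.
.scenario_leaves <- function(scenario) {
  out <- lapply(names(scenario$clades), function(nm) {
    paste0(nm, "_t", seq_len(scenario$clades[[nm]]$n_leaves))
  })
  names(out) <- names(scenario$clades)
  if (scenario$shared_leaves > 0L) {
    out$shared <- paste0("shared_t", seq_len(scenario$shared_leaves))
  }
  out
}

#' Simulate the scenario's tree
#'
#' Star model: one flat star over all leaves, unit branch lengths. Yule
#' model: each clade (and the shared pool) becomes a pure-birth subtree
#' whose branch lengths are rescaled to unit root-to-tip depth, attached
#' to the root by a stem of length 1; equalizing clade depths keeps
#' branch-length geometry from confounding the planted abundance
#' structure.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List: `tree` (a `phylo` with `L<node>` internal labels) and
#'   `clade_nodes` (named vector: for each clade its rooting node label,
#'   or the single tip name for one-leaf clades).
#' @export
scenario_tree <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  leaves <- .scenario_leaves(scenario)
  if (scenario$tree_model == "star") {
    all_tips <- unlist(leaves, use.names = FALSE)
    nwk <- paste0("(", paste0(all_tips, ":1", collapse = ","), ");")
  } else {
    subs <- vapply(leaves, function(tips) {
      n <- length(tips)
      if (n == 1L) return(paste0(tips, ":1"))
      subtr <- ape::rphylo(n, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(subtr))
      subtr$edge.length <- subtr$edge.length / depth
      subtr$tip.label <- tips
      subtr$node.label <- NULL
      sub("\\);$", "):1", ape::write.tree(subtr, digits = 12))
    }, character(1))
    nwk <- paste0("(", paste(subs, collapse = ","), ");")
  }
  tree <- parse_tree(nwk)
  tree$node.label <- paste0("L", length(tree$tip.label) + seq_len(tree$Nnode))
  labels <- .node_labels(tree)
  clade_nodes <- vapply(leaves, function(tips) {
    if (length(tips) == 1L) return(tips)
    if (scenario$tree_model == "star") return(NA_character_)  # leaf set, no rooting node
    labels[ape::getMRCA(tree, tips)]
  }, character(1))
  list(tree = tree, clade_nodes = clade_nodes)
}

#' Per-group leaf probability vectors of a scenario
#'
#' Expands the planted clade-by-group shares into full leaf probability
#' vectors. Within each clade the leaf weights are shared across groups
#' (equal, or log-normal when `within_clade_sd > 0`), so each group's
#' probability of a leaf is its clade share times the within-clade
#' weight; clade shares are reproduced exactly.
#'
#' @param scenario A `synthetic_scenario`.
#' @return Leaf x group probability matrix; columns sum to 1.
#' @export
build_profiles <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 1L)
  leaves <- .scenario_leaves(scenario)
  G <- length(scenario$groups)
  shares <- cbind(scenario$clade_shares,
                  shared = if (scenario$shared_leaves > 0L) scenario$shared_share)
  blocks <- lapply(names(leaves), function(nm) {
    n <- length(leaves[[nm]])
    wt <- if (scenario$within_clade_sd > 0)
      stats::rlnorm(n, 0, scenario$within_clade_sd) else rep(1, n)
    wt <- wt / sum(wt)
    outer(wt, shares[, nm])
  })
  prof <- do.call(rbind, blocks)
  dimnames(prof) <- list(unlist(leaves, use.names = FALSE), scenario$groups)
  stopifnot(all(abs(colSums(prof) - 1) < 1e-9))
  prof
}

#' Draw multinomial read counts from group profiles
#'
#' Each sample's counts are drawn multinomially (optionally with
#' Dirichlet overdispersion) from its group's leaf probability vector.
#'
#' @param profiles Leaf x group probability matrix ([build_profiles()]).
#' @param samples_per_group Scalar or named-per-group replicate count.
#' @param depth Scalar or named-per-group reads per sample (>= 1).
#' @param seed Optional integer seed.
#' @param overdispersion Optional Dirichlet concentration (see
#'   [synthetic_scenario()]).
#' @return List: `counts` (leaf x sample integer matrix) and `grouping`.
#' @export
sample_reads <- function(profiles, samples_per_group = 1L, depth = 1000L,
                         seed = NULL, overdispersion = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- colnames(profiles)
  sp <- if (length(samples_per_group) == 1L)
    stats::setNames(rep(samples_per_group, length(groups)), groups) else samples_per_group[groups]
  dp <- if (length(depth) == 1L)
    stats::setNames(rep(depth, length(groups)), groups) else depth[groups]
  if (any(dp < 1)) stop("depth must be >= 1", call. = FALSE)
  cols <- list(); map <- character(0)
  for (g in groups) {
    for (s in seq_len(sp[[g]])) {
      p <- profiles[, g]
      if (!is.null(overdispersion)) {
        a <- stats::rgamma(length(p), shape = overdispersion * p)
        if (sum(a) == 0) a <- p
        p <- a / sum(a)
      }
      id <- paste0(g, "_s", s)
      cols[[id]] <- stats::rmultinom(1L, dp[[g]], p)[, 1L]
      map[id] <- g
    }
  }
  counts <- do.call(cbind, cols)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(rownames(profiles), names(cols))
  list(counts = counts, grouping = new_grouping(map))
}

#' Generate a complete dataset from a scenario
#'
#' Runs [scenario_tree()], [build_profiles()] and [sample_reads()] and
#' bundles the result with the planted truth.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List: `tree`, `counts`, `grouping`, `profiles`, `truth`
#'   (planted parameters: clade shares, clade node labels, depths, seed).
#' @export
generate_dataset <- function(scenario) {
  st <- scenario_tree(scenario)
  prof <- build_profiles(scenario)
  prof <- prof[st$tree$tip.label, , drop = FALSE]
  rs_seed <- if (!is.null(scenario$seed)) scenario$seed + 2L else NULL
  rs <- sample_reads(prof, scenario$samples_per_group, scenario$depth,
                     seed = rs_seed, overdispersion = scenario$overdispersion)
  truth <- list(
    groups = scenario$groups,
    clade_shares = scenario$clade_shares,
    shared_share = scenario$shared_share,
    clade_nodes = st$clade_nodes,
    samples_per_group = scenario$samples_per_group,
    depth = scenario$depth,
    tree_model = scenario$tree_model,
    within_clade_sd = scenario$within_clade_sd,
    seed = scenario$seed
  )
  list(tree = st$tree, counts = rs$counts, grouping = rs$grouping,
       profiles = prof, truth = truth)
}

#' Three-compartment drinking-water preset
#'
#' A ready-made scenario emulating a drinking water treatment plant with
#' three compartments -- groundwater (GW), carbon filters (CF) and
#' post-chlorination (CHL) -- and two planted lineages: a
#' "treated-water" clade enriched downstream of treatment (expected
#' observation shares 4%, 68% and 58% of GW, CF and CHL reads) and a
#' near-groundwater-exclusive clade (58%, 7%, 10%), the remainder being
#' a pool shared at identical frequencies. Per-sample depths differ
#' across compartments, which is what the equal-group weighting is meant
#' to neutralize. Taxonomy strings place the planted clades in
#' candidate-phyla lineages so the subsetting defaults are exercised
#' end to end.
#'
#' @param seed Integer seed driving tree, profiles and reads.
#' @param samples_per_group Replicates per compartment (default 4).
#' @param depth Named per-group reads per sample.
#' @param n_leaves Named leaf counts for the `treated`, `gw_exclusive`
#'   and shared pools.
#' @return As [generate_dataset()], plus `taxonomy` and, in `truth`,
#'   the planted per-group shares of both lineages.
#' @export
generate_dwtp_preset <- function(seed = 1L, samples_per_group = 4L,
                                 depth = c(GW = 8000L, CF = 2000L, CHL = 4000L),
                                 n_leaves = c(treated = 12L, gw_exclusive = 10L,
                                              shared = 18L)) {
  sc <- synthetic_scenario(
    groups = c("GW", "CF", "CHL"),
    clades = list(
      treated = list(n_leaves = n_leaves[["treated"]],
                     shares = c(0.04, 0.68, 0.58)),
      gw_exclusive = list(n_leaves = n_leaves[["gw_exclusive"]],
                          shares = c(0.58, 0.07, 0.10))
    ),
    shared_leaves = n_leaves[["shared"]],
    tree_model = "yule",
    samples_per_group = samples_per_group,
    depth = depth,
    within_clade_sd = 0.5,
    seed = seed
  )
  ds <- generate_dataset(sc)

  tips <- ds$tree$tip.label
  other_cp <- c("Microgenomates", "Saccharibacteria", "Dependentiae",
                "OP3", "OP1", "BRC1", "WS3")
  non_cp <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes")
  lineage <- character(length(tips))
  treated_tips <- grepl("^treated_", tips)
  gw_tips <- grepl("^gw_exclusive_", tips)
  shared_tips <- grepl("^shared_", tips)
  lineage[treated_tips] <- "Bacteria;Parcubacteria;Parcubacteria_genera_incertae_sedis"
  lineage[gw_tips] <- paste0("Bacteria;",
                             rep_len(other_cp, sum(gw_tips)), ";unclassified")
  n_sh <- sum(shared_tips)
  sh_phy <- c(rep("Parcubacteria", ceiling(n_sh / 3)),
              rep_len(non_cp, n_sh - ceiling(n_sh / 3)))
  lineage[shared_tips] <- paste0("Bacteria;", sh_phy, ";unclassified")
  set.seed(seed + 3L)
  ds$taxonomy <- data.frame(
    otu_id = tips, lineage = lineage,
    confidence = round(stats::runif(length(tips), 0.8, 1), 3),
    stringsAsFactors = FALSE
  )
  ds$truth$planted <- list(
    treated = list(node = ds$truth$clade_nodes[["treated"]],
                   shares = c(GW = 0.04, CF = 0.68, CHL = 0.58)),
    gw_exclusive = list(node = ds$truth$clade_nodes[["gw_exclusive"]],
                        shares = c(GW = 0.58, CF = 0.07, CHL = 0.10))
  )
  ds
}

#' Write a synthetic dataset to a directory
#'
#' Writes `tree.nwk`, `counts.tsv`, `groups.tsv`, `taxonomy.tsv` (when
#' present) and `truth.json` (planted parameters).
#'
#' @param dataset Output of [generate_dataset()] or
#'   [generate_dwtp_preset()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  write_grouping(dataset$grouping, file.path(dir, "groups.tsv"))
  if (!is.null(dataset$taxonomy)) {
    utils::write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- dataset$truth
  truth$clade_shares <- as.data.frame(truth$clade_shares)
  # keep names of atomic vectors (clade_nodes, depths, shares) as JSON keys
  truth <- rapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  }, how = "replace")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
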