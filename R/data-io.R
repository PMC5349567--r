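#' Parse a rooted phylogenetic tree from newick text
#'
#' Reads a newick string into an [ape::phylo] object and validates it for
#' use in entropy partitioning: a single root, unique non-empty leaf
#' labels, and nonnegative branch lengths. Internal node labels are
#' preserved; they become lineage identifiers in reports. Missing branch
#' lengths are set to 0 with a warning (a zero-length branch contributes
#' nothing to phylogenetic entropy).
#'
#' @param newick_text Character scalar holding a newick tree description.
#' @return A rooted `phylo` object with an `edge.length` component.
#' @examples
#' tr <- parse_tree("((A:1,B:1)N1:1,C:2);")
#' @export
parse_tree <- function(newick_text) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = newick_text)),
    error = function(e) stop("malformed newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed newick: could not parse tree text", call. = FALSE)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got ", length(tree), call. = FALSE)
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting them to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  # every parsed newick has a unique root node; polytomies (incl. a star
  # root) are legitimate here
  tree
}

#' Write a tree to newick text
#'
#' Inverse of [parse_tree()]; internal node labels and branch lengths are
#' preserved so that a write/parse round trip reproduces the tree.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

.read_tsv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty table", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(cells)
  if (length(unique(width)) != 1L) {
    stop("ragged rows: widths ", paste(unique(width), collapse = ", "), call. = FALSE)
  }
  do.call(rbind, cells)
}

#' Parse an OTU-by-sample read count table
#'
#' Expects tab-separated text with a header row of sample ids and a first
#' column of OTU ids; remaining cells are nonnegative integer read counts.
#' Lines starting with `#` are ignored. Sample columns with zero total
#' reads are rejected: every sample must carry at least one observation.
#'
#' @param tsv_text Character scalar with the table text.
#' @return Integer matrix (OTUs x samples) with dimnames.
#' @export
parse_count_table <- function(tsv_text) {
  m <- .read_tsv(tsv_text)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("count table needs a header row and at least one OTU row", call. = FALSE)
  samples <- m[1, -1]
  otus <- m[-1, 1]
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(otus)) stop("duplicate OTU ids", call. = FALSE)
  body <- m[-1, -1, drop = FALSE]
  suppressWarnings(num <- as.numeric(body))
  if (anyNA(num)) stop("non-numeric count cell", call. = FALSE)
  if (any(num < 0)) stop("negative count", call. = FALSE)
  if (any(num != round(num))) stop("non-integer count", call. = FALSE)
  counts <- matrix(as.integer(num), nrow = nrow(body), ncol = ncol(body),
                   dimnames = list(unname(otus), unname(samples)))
  zero <- colSums(counts) == 0L
  if (any(zero)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  counts
}

#' Write a count table as TSV
#'
#' @param counts Integer matrix as returned by [parse_count_table()].
#' @param file Optional path; if `NULL` the TSV text is returned.
#' @param id_column Name of the leading OTU id column in the header.
#' @return TSV text, invisibly when written to a file.
#' @export
write_count_table <- function(counts, file = NULL, id_column = "otu_id") {
  header <- paste(c(id_column, colnames(counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t")
  }, character(1))
  txt <- paste(c(header, rows), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse a sample-to-group mapping
#'
#' Two tab-separated columns, `sample` and `group` (a header line is
#' optional and detected by the literal column names). Every sample in
#' `samples` must be mapped and every group must contain at least one
#' sample. Group weights default to equal, `1/G`: with equal weights each
#' group contributes the same to pooled diversity estimates regardless of
#' its read depth.
#'
#' @param tsv_text Character scalar with the mapping text.
#' @param samples Character vector of sample ids that must be covered
#'   (typically `colnames(counts)`); `NULL` to accept the mapping as is.
#' @param weights Either `"equal"` (default) or a named numeric vector of
#'   group weights summing to 1.
#' @return An object of class `grouping`: a list with `sample`, `group`
#'   (parallel character vectors), `groups` (ordered unique group names)
#'   and `weights` (named, summing to 1).
#' @export
parse_grouping <- function(tsv_text, samples = NULL, weights = "equal") {
  m <- .read_tsv(tsv_text)
  if (ncol(m) != 2L) stop("grouping must have exactly two columns: sample, group", call. = FALSE)
  if (identical(tolower(m[1, 1]), "sample")) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty grouping", call. = FALSE)
  new_grouping(stats::setNames(m[, 2], m[, 1]), samples = samples, weights = weights)
}

#' Construct a grouping from a named vector
#'
#' @param map Named character vector, `sample -> group`.
#' @inheritParams parse_grouping
#' @return A `grouping` object; see [parse_grouping()].
#' @export
new_grouping <- function(map, samples = NULL, weights = "equal") {
  sample_ids <- names(map)
  if (is.null(sample_ids) || any(!nzchar(sample_ids))) stop("samples must be named", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample in grouping", call. = FALSE)
  group <- as.character(map)
  if (any(!nzchar(group))) stop("empty group label", call. = FALSE)
  if (!is.null(samples)) {
    missing <- setdiff(samples, sample_ids)
    if (length(missing)) {
      stop("sample(s) missing from grouping: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    keep <- sample_ids %in% samples
    sample_ids <- sample_ids[keep]
    group <- group[keep]
  }
  groups <- unique(group)
  if (identical(weights, "equal")) {
    w <- stats::setNames(rep(1 / length(groups), length(groups)), groups)
  } else {
    if (is.null(names(weights)) || !setequal(names(weights), groups)) {
      stop("weights must be named by group", call. = FALSE)
    }
    w <- weights[groups]
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) stop("weights must be positive and sum to 1", call. = FALSE)
  }
  structure(
    list(sample = sample_ids, group = group, groups = groups, weights = w),
    class = "grouping"
  )
}

#' @export
print.grouping <- function(x, ...) {
  cat("grouping:", length(x$sample), "samples in", length(x$groups), "groups\n")
  tab <- table(factor(x$group, levels = x$groups))
  for (g in x$groups) {
    cat(sprintf("  %s: %d sample(s), weight %.4g\n", g, tab[[g]], x$weights[[g]]))
  }
  invisible(x)
}

#' Write a grouping as TSV
#' @param grouping A `grouping` object.
#' @param file Optional path; if `NULL` the TSV text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
write_grouping <- function(grouping, file = NULL) {
  txt <- paste(c("sample\tgroup", paste(grouping$sample, grouping$group, sep = "\t")),
               collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse an OTU taxonomy table
#'
#' Three tab-separated columns: OTU id, semicolon-delimited lineage string
#' of ranked names, and a classifier confidence in `[0, 1]` (e.g. RDP
#' bootstrap confidence). A header line starting with `otu_id` is skipped.
#'
#' @param tsv_text Character scalar with the table text.
#' @return A data.frame with columns `otu_id`, `lineage`, `confidence`.
#' @export
parse_taxonomy <- function(tsv_text) {
  m <- .read_tsv(tsv_text)
  if (ncol(m) != 3L) stop("taxonomy must have three columns: otu_id, lineage, confidence", call. = FALSE)
  if (identical(tolower(m[1, 1]), "otu_id")) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty taxonomy", call. = FALSE)
  if (anyDuplicated(m[, 1])) stop("duplicate OTU id in taxonomy", call. = FALSE)
  if (any(!nzchar(trimws(m[, 2])))) stop("empty lineage string", call. = FALSE)
  suppressWarnings(conf <- as.numeric(m[, 3]))
  if (anyNA(conf)) stop("non-numeric confidence", call. = FALSE)
  if (any(conf < 0 | conf > 1)) stop("confidence outside [0, 1]", call. = FALSE)
  data.frame(otu_id = unname(m[, 1]), lineage = unname(m[, 2]),
             confidence = conf, stringsAsFactors = FALSE)
}

#' Read and parse the standard inputs from files
#'
#' Convenience wrappers around the `parse_*` functions.
#'
#' @param file Path to the input file.
#' @param samples,weights Passed through to [parse_grouping()].
#' @return See the corresponding `parse_*` function.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_tree <- function(file) parse_tree(paste(readLines(file, warn = FALSE), collapse = "\n"))

#' @rdname read_inputs
#' @export
read_count_table <- function(file) parse_count_table(paste(readLines(file, warn = FALSE), collapse = "\n"))

#' @rdname read_inputs
#' @export
read_grouping <- function(file, samples = NULL, weights = "equal") {
  parse_grouping(paste(readLines(file, warn = FALSE), collapse = "\n"), samples, weights)
}

#' @rdname read_inputs
#' @export
read_taxonomy <- function(file) parse_taxonomy(paste(readLines(file, warn = FALSE), collapse = "\n"))
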