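#' Second-level agglomeration of sequence clusters into NSCs
#'
#' Network sequence clusters (NSCs) are the connected components of the graph
#' that links two first-level clusters whenever their pairwise percent
#' identity reaches a threshold (97% by default, applied inclusively).
#' Transitive linkage applies: A joins C through B even when A and C are below
#' the threshold. NSC ids are canonical: each NSC is named after its
#' lexicographically smallest member, so the result is invariant to input row
#' order.
#'
#' @param sim a similarity matrix: either a `"similarity_matrix"` object from
#'   [generate_similarity_matrix()] / [read_similarity_matrix()], or a plain
#'   symmetric numeric matrix with identical row/column names and diagonal
#'   100.
#' @param threshold percent identity at or above which two clusters are
#'   linked.
#' @return a list of class `"nsc_assignment"` with `member_map` (named
#'   character vector: input id -> NSC id) and `nsc_ids` (sorted unique NSC
#'   ids).
#' @examples
#' m <- matrix(c(100, 97.5, 90, 97.5, 100, 97.2, 90, 97.2, 100), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' build_nscs(m)$member_map  # one NSC {A, B, C} by transitive linkage
#' @export
build_nscs <- function(sim, threshold = 97) {
  identity <- if (inherits(sim, "similarity_matrix")) sim$identity else sim
  if (length(identity) == 0 || nrow(identity) == 0)
    return(structure(list(member_map = character(0), nsc_ids = character(0)),
                     class = "nsc_assignment"))
  if (!isSymmetric(unname(identity)))
    stop("similarity matrix must be symmetric")
  ids <- rownames(identity)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_len(nrow(identity)))
  adj <- identity >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  member_map <- vapply(split(ids, comp), min, character(1))[as.character(comp)]
  names(member_map) <- ids
  structure(list(member_map = member_map,
                 nsc_ids = sort(unique(member_map))),
            class = "nsc_assignment")
}

#' Sum member counts into NSC rows
#'
#' Collapses a first-level-cluster count table to the NSC level by summing,
#' element-wise, the rows of all members of each NSC. Total reads are
#' conserved per sample and overall.
#'
#' @param counts taxa-by-sample integer matrix (rownames = input cluster ids).
#' @param assignment an `"nsc_assignment"` from [build_nscs()].
#' @return an NSC-by-sample count matrix whose rows follow `assignment$nsc_ids`.
#' @export
aggregate_counts <- function(counts, assignment) {
  assert_count_table(counts)
  unmapped <- setdiff(rownames(counts), names(assignment$member_map))
  if (length(unmapped))
    stop("count rows missing from NSC assignment: ",
         paste(unmapped, collapse = ", "))
  nsc <- assignment$member_map[rownames(counts)]
  out <- rowsum(counts, group = nsc, reorder = TRUE)
  storage.mode(out) <- "integer"
  out[assignment$nsc_ids[assignment$nsc_ids %in% rownames(out)], , drop = FALSE]
}

#' Drop rows whose total read abundance is too small
#'
#' Removes NSCs supported by fewer than `min_total` reads across all samples
#' (the default keeps a row with exactly 3 reads). Row order of survivors is
#' preserved.
#'
#' @param counts taxa-by-sample integer matrix.
#' @param min_total minimum total reads for a row to be retained.
#' @return the filtered count matrix.
#' @export
filter_min_abundance <- function(counts, min_total = 3) {
  assert_count_table(counts)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Retain only rows on a precomputed keep-list
#'
#' A pass-through filter for retention decisions made outside the package
#' (e.g. taxonomic database matching): rows whose id appears in `keep_ids`
#' are kept, in their original order.
#'
#' @param counts taxa-by-sample integer matrix.
#' @param keep_ids character vector of row ids to retain.
#' @return the filtered count matrix.
#' @export
filter_allowlist <- function(counts, keep_ids) {
  assert_count_table(counts)
  counts[rownames(counts) %in% keep_ids, , drop = FALSE]
}
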