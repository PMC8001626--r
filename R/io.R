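#' Read / write taxa-by-sample tables
#'
#' Tables are tab-separated with row ids in the first column and a header row
#' of sample ids: taxa (or parameters) in rows, samples in columns.
#'
#' @param path file path.
#' @return `read_count_table()` an integer matrix; `read_env_table()` a
#'   numeric matrix.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  assert_count_table(m)
  m
}

#' @rdname table_io
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' @rdname table_io
#' @param x matrix to write (row ids become the first column, `id`).
#' @export
write_table_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square percent-identity matrix
#'
#' TSV with identical row and column ids; values in `[0, 100]`, diagonal 100.
#'
#' @param path file path.
#' @return a `"similarity_matrix"` object.
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("similarity matrix must be square with matching ids")
  structure(list(ids = rownames(m), identity = m, truth = NULL),
            class = "similarity_matrix")
}

#' Write / read a consensus network as GraphML
#'
#' GraphML is the canonical graph format (attribute-rich and portable to
#' other network tools); [write_edge_list()] provides a lightweight TSV
#' mirror. Logical vertex attributes survive the round trip as 0/1 and are
#' restored to logical on read.
#'
#' @param net an igraph graph.
#' @param path file path.
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
write_graphml <- function(net, path) {
  g <- net
  # GraphML has no logical type in igraph's writer; store as integer
  if ("is_env" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "is_env",
                                 value = as.integer(igraph::V(g)$is_env))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname graph_io
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("is_env" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "is_env",
                                 value = as.logical(as.integer(igraph::V(g)$is_env)))
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  g
}

#' @rdname graph_io
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Counts and environmental parameters as TSV, ground truth as JSON, season
#' assignment as a two-column TSV.
#'
#' @param sim a `"synthetic_dataset"` from [generate_counts()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(sim$counts, file.path(dir, "counts.tsv"))
  if (nrow(sim$env) > 0)
    write_table_tsv(sim$env, file.path(dir, "env.tsv"))
  utils::write.table(
    data.frame(sample = names(sim$seasons), season = as.character(sim$seasons)),
    file.path(dir, "seasons.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    guild_membership = as.list(sim$truth$guild_membership),
    planted_edges = apply(sim$truth$planted_edges, 1,
                          function(r) paste(r, collapse = "--")),
    env_links = sim$truth$env_links)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
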