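#' Graph-topology report for a co-occurrence network
#'
#' Computes the standard descriptors of network complexity on an undirected,
#' unweighted view of the graph:
#' average degree `2E/N`; density `2E/(N(N-1))`; global transitivity
#' (3 x triangles / connected triples); average shortest-path length over
#' connected node pairs only (the networks are typically multi-component, so
#' infinite distances are excluded rather than imputed); diameter as the
#' maximum finite shortest-path length; modularity of a seeded Louvain
#' partition; and connected-component counts by size class.
#'
#' @param net an igraph graph (e.g. from [build_consensus()]).
#' @param modularity_seed seed for the Louvain community detection.
#' @return a list of class `"topology_report"` with fields `n_nodes`,
#'   `n_env_nodes`, `n_edges`, `average_degree`, `average_path_length`,
#'   `density`, `diameter`, `modularity`, `transitivity`, `components_total`,
#'   `components_gt3` (components with more than 3 nodes), `components_pairs`
#'   (two-node components), `single_node` (flag: path metrics degenerate).
#' @export
compute_topology <- function(net, modularity_seed = 1L) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  n <- igraph::vcount(net)
  if (n == 0) stop("empty graph")
  e <- igraph::ecount(net)
  is_env <- igraph::vertex_attr(net, "is_env")
  n_env <- if (is.null(is_env)) 0L else sum(is_env, na.rm = TRUE)
  single <- n == 1
  avg_degree <- 2 * e / n
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  trans <- igraph::transitivity(net, type = "global")
  if (is.nan(trans)) trans <- 0
  if (single || e == 0) {
    apl <- 0
    diam <- 0
  } else {
    d <- igraph::distances(net, weights = NA)
    finite <- d[upper.tri(d)]
    finite <- finite[is.finite(finite) & finite > 0]
    apl <- if (length(finite)) mean(finite) else 0
    diam <- if (length(finite)) max(finite) else 0
  }
  set.seed(modularity_seed)
  mod <- if (e > 0) {
    cl <- igraph::cluster_louvain(net, weights = NA)
    igraph::modularity(net, igraph::membership(cl),
                       weights = rep(1, igraph::ecount(net)))
  } else 0
  comp <- igraph::components(net)
  sizes <- comp$csize
  structure(list(n_nodes = n, n_env_nodes = as.integer(n_env), n_edges = e,
                 average_degree = avg_degree, average_path_length = apl,
                 density = density, diameter = as.integer(diam),
                 modularity = mod, transitivity = trans,
                 components_total = comp$no,
                 components_gt3 = sum(sizes > 3),
                 components_pairs = sum(sizes == 2),
                 single_node = single),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Network topology: %d nodes (%d environmental), %d edges\n",
    "  average degree       %.2f\n  density              %.3f\n",
    "  average path length  %.2f\n  diameter             %d\n",
    "  transitivity         %.2f\n  modularity (Louvain) %.2f\n",
    "  components           %d total, %d > 3 nodes, %d pairs\n"),
    x$n_nodes, x$n_env_nodes, x$n_edges, x$average_degree, x$density,
    x$average_path_length, x$diameter, x$transitivity, x$modularity,
    x$components_total, x$components_gt3, x$components_pairs))
  invisible(x)
}

#' Unweighted betweenness centrality
#'
#' Shortest-path betweenness on the unweighted graph (edge correlation
#' weights are ignored because path distances are counted in numbers of
#' edges): for each node, the number of shortest paths between other node
#' pairs passing through it, endpoints excluded, unnormalized. Pairs in
#' different components contribute nothing.
#'
#' @param net an igraph graph.
#' @return a named numeric vector of betweenness scores.
#' @export
node_betweenness <- function(net) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  if (igraph::vcount(net) == 0) stop("empty graph")
  b <- igraph::betweenness(net, directed = FALSE, weights = NA,
                           normalized = FALSE)
  if (is.null(names(b)))
    names(b) <- as.character(seq_along(b))
  b
}

#' Articulation points
#'
#' Nodes whose removal increases the number of connected components.
#'
#' @param net an igraph graph.
#' @return a character vector of node names (possibly empty).
#' @export
find_articulation_points <- function(net) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  if (igraph::vcount(net) == 0) stop("empty graph")
  ap <- igraph::articulation_points(net)
  nm <- igraph::vertex_attr(net, "name")
  if (is.null(nm)) as.character(as.integer(ap)) else nm[as.integer(ap)]
}

#' Extract the subnetwork around a focal node
#'
#' Induced subgraph on the focal node and all of its direct neighbors,
#' retaining focal-neighbor edges and all edges the neighbors share amongst
#' each other.
#'
#' @param net an igraph graph with named vertices.
#' @param focal name of the focal node.
#' @return an igraph graph (a single-node graph if the focal is isolated).
#' @export
extract_subnetwork <- function(net, focal) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  if (!focal %in% nm) stop("focal node not in network: ", focal)
  nb <- igraph::neighbors(net, focal)
  igraph::induced_subgraph(net, c(igraph::V(net)[focal], nb))
}
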