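#' Cascading targeted attack on a network
#'
#' Species-extinction simulation: at each step the node with the current
#' highest betweenness centrality is removed (ties broken by
#' lexicographically smallest node id), betweenness is recalculated on the
#' remaining graph, and the cumulative loss of connectivity is recorded. Two
#' loss metrics are emitted: the primary `loss_fraction` is the fraction of
#' the network's initial edges eliminated; the secondary
#' `pair_loss_fraction` is the fraction of initially connected node pairs no
#' longer connected (nodes isolated by removals stay in the graph; only
#' explicit removals count toward the rank).
#'
#' @param net an igraph graph (non-empty).
#' @param n_removals number of nodes to remove (default: all).
#' @param order optional character vector of node ids to remove in the given
#'   order instead of the betweenness-ranked cascade (used for random-attack
#'   baselines).
#' @return a data frame of class `"attack_curve"` with columns `rank`,
#'   `removed_node`, `betweenness_at_removal`, `edges_remaining`,
#'   `loss_fraction`, `pair_loss_fraction`; attribute `initial_edges`.
#' @export
cascading_attack <- function(net, n_removals = igraph::vcount(net),
                             order = NULL) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  n <- igraph::vcount(net)
  if (n == 0) stop("empty graph")
  if (n_removals > n) stop("n_removals exceeds the number of nodes")
  if (is.null(igraph::V(net)$name))
    net <- igraph::set_vertex_attr(net, "name",
                                   value = sprintf("n%04d", seq_len(n)))
  if (!is.null(order)) {
    if (length(order) < n_removals) stop("order shorter than n_removals")
    if (!all(order[seq_len(n_removals)] %in% igraph::V(net)$name))
      stop("order contains unknown node ids")
  }
  e0 <- igraph::ecount(net)
  p0 <- connected_pairs(net)
  g <- net
  steps <- vector("list", n_removals)
  for (k in seq_len(n_removals)) {
    bw <- node_betweenness(g)
    if (is.null(order)) {
      # highest betweenness; ties -> lexicographically smallest id
      top <- names(bw)[bw == max(bw)]
      victim <- min(top)
    } else {
      victim <- order[k]
    }
    b_at <- unname(bw[victim])
    g <- igraph::delete_vertices(g, victim)
    er <- igraph::ecount(g)
    steps[[k]] <- data.frame(
      rank = k, removed_node = victim, betweenness_at_removal = b_at,
      edges_remaining = er,
      loss_fraction = if (e0 > 0) 1 - er / e0 else 0,
      pair_loss_fraction = if (p0 > 0) 1 - connected_pairs(g) / p0 else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, steps)
  attr(out, "initial_edges") <- e0
  attr(out, "initial_pairs") <- p0
  class(out) <- c("attack_curve", "data.frame")
  out
}

# number of unordered node pairs connected by some path
connected_pairs <- function(g) {
  sizes <- igraph::components(g)$csize
  sum(sizes * (sizes - 1) / 2)
}

#' Removals needed to reach given connectivity-loss levels
#'
#' For each loss level, the smallest removal rank at which the attack curve's
#' `loss_fraction` reaches the level; `NA` if the level is never reached
#' within the curve.
#'
#' @param curve an `"attack_curve"` from [cascading_attack()].
#' @param loss_levels numeric vector of levels in `(0, 1]`
#'   (default `c(0.5, 0.95)`).
#' @return a named integer vector (names are the levels).
#' @export
attack_summary <- function(curve, loss_levels = c(0.5, 0.95)) {
  if (nrow(curve) == 0) stop("empty attack curve")
  if (any(loss_levels <= 0) || any(loss_levels > 1))
    stop("loss levels must lie in (0, 1]")
  out <- vapply(loss_levels, function(lv) {
    hit <- which(curve$loss_fraction >= lv)
    if (length(hit)) as.integer(curve$rank[hit[1]]) else NA_integer_
  }, integer(1))
  names(out) <- format(loss_levels)
  out
}
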