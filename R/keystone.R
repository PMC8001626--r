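#' Identify key (keystone) nodes
#'
#' A key node has betweenness centrality significantly higher than expected
#' from the network's betweenness distribution AND is an articulation point.
#' Significance is assessed by bootstrapping: the vector of node betweenness
#' scores is resampled with replacement `n_boot` times, the bootstrap
#' distribution of the mean betweenness is formed, and a node is significant
#' when its betweenness exceeds the upper bound of the central `ci`
#' percentile interval of that distribution. When all nodes have equal
#' betweenness the interval collapses onto the common value and no node is
#' significant.
#'
#' @param net an igraph graph with at least 3 nodes.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param ci central confidence level for the percentile interval
#'   (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return a data frame of class `"key_node_report"` with one row per node:
#'   `node`, `betweenness`, `is_articulation`, `significant`,
#'   `is_key = significant & is_articulation`; attributes `ci_upper`,
#'   `ci_lower`, `n_boot`, `ci`, `seed`.
#' @export
find_key_nodes <- function(net, n_boot = 10000, ci = 0.95, seed = 1L) {
  if (!igraph::is_igraph(net)) stop("expected an igraph graph")
  if (igraph::vcount(net) < 3) stop("at least 3 nodes are required")
  bw <- node_betweenness(net)
  set.seed(seed)
  bt <- boot::boot(bw, statistic = function(d, i) mean(d[i]), R = n_boot)
  qq <- stats::quantile(bt$t[, 1], c((1 - ci) / 2, (1 + ci) / 2),
                        names = FALSE)
  ci_upper <- qq[2]
  arts <- find_articulation_points(net)
  significant <- bw > ci_upper
  out <- data.frame(node = names(bw), betweenness = unname(bw),
                    is_articulation = names(bw) %in% arts,
                    significant = unname(significant),
                    is_key = unname(significant) & names(bw) %in% arts,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "ci_lower") <- qq[1]
  attr(out, "ci_upper") <- ci_upper
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "ci") <- ci
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("key_node_report", "data.frame")
  out
}
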