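# Brute-force graph oracles, written independently of igraph so the package's
# metric implementations can be checked against exhaustive enumeration on
# small graphs. All oracles take a symmetric 0/1 adjacency matrix.

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  a
}

adjacency_to_graph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# all-pairs shortest-path distances by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_apl <- function(a) {
  d <- oracle_distances(a)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v)) mean(v) else 0
}

oracle_diameter <- function(a) {
  d <- oracle_distances(a)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v)) max(v) else 0
}

# global transitivity: 3 * triangles / connected triples
oracle_transitivity <- function(a) {
  n <- nrow(a)
  triangles <- 0
  triples <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i < j && j < k) {
      e <- a[i, j] + a[j, k] + a[i, k]
      if (e == 3) triangles <- triangles + 1
    }
  }
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  3 * triangles / triples
}

# betweenness by explicit shortest-path counting (endpoints excluded)
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  # sigma[s, t]: number of shortest s-t paths, by dynamic programming over
  # increasing distance from s
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (t in reach[order(d[s, reach])]) {
      if (t == s) next
      preds <- which(a[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bw <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s >= t || !is.finite(d[s, t])) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  names(bw) <- rownames(a)
  bw
}

oracle_n_components <- function(a) {
  n <- nrow(a)
  if (n == 0) return(0)
  seen <- rep(FALSE, n)
  comps <- 0
  for (start in 1:n) {
    if (seen[start]) next
    comps <- comps + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(a[v, ] == 1 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# component labels via union-find on the thresholded relation
oracle_components <- function(a) {
  n <- nrow(a)
  parent <- 1:n
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in 1:n) for (j in 1:n)
    if (a[i, j] == 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  vapply(1:n, find, integer(1))
}

oracle_articulation <- function(a) {
  n <- nrow(a)
  base <- oracle_n_components(a)
  out <- character(0)
  for (v in 1:n) {
    sub <- a[-v, -v, drop = FALSE]
    if (oracle_n_components(sub) > base) out <- c(out, rownames(a)[v])
  }
  out
}

# tie-corrected Spearman rho from the textbook rank formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# helper: canonical "a--b" keys for an igraph's edge set
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1,
        paste, collapse = "--")
}

# two dense clusters joined through a single bridge node; used as the
# targeted-attack benchmark
two_guild_benchmark <- function(k = 8) {
  g1 <- igraph::make_full_graph(k)
  igraph::V(g1)$name <- sprintf("a%02d", 1:k)
  g2 <- igraph::make_full_graph(k)
  igraph::V(g2)$name <- sprintf("b%02d", 1:k)
  g <- igraph::disjoint_union(g1, g2)
  g <- igraph::add_vertices(g, 1, name = "bridge")
  igraph::add_edges(g, c("a01", "bridge", "bridge", "b01"))
}
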