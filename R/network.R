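#' Pairwise Spearman correlation matrix over samples
#'
#' Computes tie-corrected Spearman rank correlation (Pearson correlation of
#' average ranks) between every pair of rows. Rows that are constant across
#' samples have undefined rank correlation; their entries (including the
#' diagonal) are `NA`, never coerced to 0.
#'
#' @param norm a `"normalized_table"` or a plain numeric matrix
#'   (features in rows, samples in columns) with at least 3 samples.
#' @return a symmetric numeric matrix of Spearman rho with `NA` for undefined
#'   pairs.
#' @export
spearman_matrix <- function(norm) {
  x <- if (inherits(norm, "normalized_table")) norm$values else norm
  if (!is.matrix(x)) stop("expected a matrix or normalized_table")
  if (ncol(x) < 3) stop("at least 3 samples are required")
  r <- row_ranks(x)
  constant <- apply(x, 1L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(t(r)))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}

# internal: Spearman rho of a matrix after row-wise jitter; amplitude is a
# per-row vector (0 rows stay untouched)
jittered_spearman <- function(x, amp) {
  noise <- matrix(stats::runif(length(x), -1, 1), nrow(x), ncol(x)) * amp
  suppressWarnings(stats::cor(t(row_ranks(x + noise))))
}

#' Dataset-specific Spearman rho significance thresholds from a permutation
#' null model
#'
#' Builds a null model of the normalized table: in each permutation every
#' row's values are shuffled independently across samples (destroying all
#' between-row association) and perturbed with uniform low-level noise to
#' break rank ties. The null distribution of pairwise rho determines the
#' smallest correlation magnitudes at which the expected number of null edges
#' (co-occurrences and co-exclusions combined) does not exceed `alpha` times
#' the number of tested pairs: `rho_pos` is the mean over permutations of the
#' per-permutation `1 - alpha/2` quantile of null rho, and `rho_neg` the mean
#' `alpha/2` quantile -- the tolerance splits evenly between the two tails,
#' since an edge may pass on either side. This replaces an arbitrary
#' fixed rho cutoff with thresholds calibrated to the dataset's dimensions
#' and rank-tie structure.
#'
#' @param norm a `"normalized_table"` (taxa and, optionally, environmental
#'   parameter rows).
#' @param n_permutations number of null permutations (at least 100 for stable
#'   quantiles; 1000 by default).
#' @param alpha tolerated expected fraction of false edges among tested
#'   pairs.
#' @param seed integer seed; thresholds are deterministic given it.
#' @param jitter_scale tie-breaking noise amplitude as a multiple of each
#'   row's interquartile range (default `1e-6`, far below signal scale).
#' @return an object of class `"threshold_result"`: `rho_pos`, `rho_neg`,
#'   `n_permutations`, `alpha`, `null_quantiles` (per-permutation extreme-rho
#'   summaries: the `alpha` and `1 - alpha` quantiles and the min/max null
#'   rho), `seed`, `jitter_scale`.
#' @export
determine_thresholds <- function(norm, n_permutations = 1000, alpha = 0.01,
                                 seed = 1L, jitter_scale = 1e-6) {
  stopifnot(inherits(norm, "normalized_table"))
  x <- norm$values
  if (n_permutations < 100)
    stop("n_permutations must be at least 100 for stable quantiles")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  amp <- jitter_amplitudes(x, jitter_scale)
  if (all(amp == 0))
    stop("degenerate data: every row is constant across samples")
  n <- ncol(x)
  m <- nrow(x)
  ut <- upper.tri(matrix(0, m, m))
  set.seed(seed)
  q <- matrix(NA_real_, n_permutations, 4,
              dimnames = list(NULL, c("q_lo", "q_hi", "min", "max")))
  for (p in seq_len(n_permutations)) {
    xp <- t(apply(x, 1L, function(v) v[sample.int(n)]))
    rho <- jittered_spearman(xp, amp)[ut]
    rho <- rho[!is.na(rho)]
    qq <- stats::quantile(rho, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    q[p, ] <- c(qq[1], qq[2], min(rho), max(rho))
  }
  res <- list(rho_pos = mean(q[, "q_hi"]), rho_neg = mean(q[, "q_lo"]),
              n_permutations = as.integer(n_permutations), alpha = alpha,
              null_quantiles = as.data.frame(q), seed = as.integer(seed),
              jitter_scale = jitter_scale)
  if (!(res$rho_neg < 0 && res$rho_pos > 0))
    warning("null thresholds do not bracket zero; data may be degenerate")
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rho thresholds (alpha = %g, %d permutations):\n  co-occurrence  %.2f\n  co-exclusion  %.2f\n",
    x$alpha, x$n_permutations, x$rho_pos, x$rho_neg))
  invisible(x)
}

#' Build the persistence-filtered consensus co-occurrence network
#'
#' Correlates `n_jitter` noise-jittered replicates of the observed table and
#' keeps an edge only if its rho passes the significance threshold
#' (`rho >= rho_pos` for co-occurrence, `rho <= rho_neg` for co-exclusion) in
#' more than `persistence_cutoff` of the replicates. Edge weight is the mean
#' rho over the passing replicates. Nodes not incident to any retained edge
#' are dropped. The jitter amplitude is the same tie-breaking scale used for
#' the null model, so persistence measures stability of an edge against rank
#' ties, not against signal-scale noise.
#'
#' @param norm the `"normalized_table"` the thresholds were computed on.
#' @param thresholds a `"threshold_result"` from [determine_thresholds()].
#' @param n_jitter number of jittered replicates (default 100).
#' @param persistence_cutoff an edge must pass in strictly more than this
#'   fraction of replicates, in `(0, 1]`.
#' @param seed integer seed.
#' @return an [igraph][igraph::igraph-package] undirected graph with vertex
#'   attributes `name`, `is_env`, `abundance` (total reads; `NA` for
#'   parameter nodes) and edge attributes `rho` (mean over passing
#'   replicates), `sign` (+1/-1) and `persistence`.
#' @export
build_consensus <- function(norm, thresholds, n_jitter = 100,
                            persistence_cutoff = 0.5, seed = 1L) {
  stopifnot(inherits(norm, "normalized_table"),
            inherits(thresholds, "threshold_result"))
  if (persistence_cutoff <= 0 || persistence_cutoff > 1)
    stop("persistence_cutoff must lie in (0, 1]")
  if (n_jitter < 1) stop("n_jitter must be positive")
  x <- norm$values
  m <- nrow(x)
  amp <- jitter_amplitudes(x, thresholds$jitter_scale)
  set.seed(seed)
  pass_count <- matrix(0, m, m)
  rho_sum <- matrix(0, m, m)
  for (r in seq_len(n_jitter)) {
    rho <- jittered_spearman(x, amp)
    pass <- (rho >= thresholds$rho_pos) | (rho <= thresholds$rho_neg)
    pass[is.na(pass)] <- FALSE
    diag(pass) <- FALSE
    pass_count <- pass_count + pass
    rho_sum <- rho_sum + ifelse(pass, rho, 0)
  }
  persistence <- pass_count / n_jitter
  sel <- which(persistence > persistence_cutoff & upper.tri(persistence),
               arr.ind = TRUE)
  ids <- rownames(x)
  if (nrow(sel) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  mean_rho <- rho_sum[sel] / pass_count[sel]
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      rho = mean_rho, sign = ifelse(mean_rho >= 0, 1L, -1L),
                      persistence = persistence[sel])
  nodes <- sort(unique(c(edges$from, edges$to)))
  vertices <- data.frame(name = nodes,
                         is_env = unname(norm$is_env[nodes]),
                         abundance = unname(norm$row_totals[nodes]))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
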