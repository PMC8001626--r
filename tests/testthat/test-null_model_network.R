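as_norm <- function(values, is_env = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("r%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(is_env)) is_env <- rep(FALSE, nrow(values))
  structure(list(values = values,
                 is_env = stats::setNames(is_env, rownames(values)),
                 row_totals = stats::setNames(rowSums(abs(values)),
                                              rownames(values)),
                 variant = "test"),
            class = "normalized_table")
}

test_that("spearman matrix: identity, reversal, hand-computed ties", {
  x <- rbind(a = c(1, 4, 2, 8, 5, 7),
             b = c(9, 6, 8, 2, 5, 3),  # strictly decreasing transform of a
             c = c(1, 1, 2, 3, 4, 5))  # one tie in row c
  rho <- spearman_matrix(x)
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(unname(rho["a", "b"]), -1)
  # tie-corrected rank formula computed independently
  expect_equal(unname(rho["a", "c"]), oracle_spearman(x["a", ], x["c", ]))
  expect_equal(unname(rho["b", "c"]), oracle_spearman(x["b", ], x["c", ]))
  expect_true(isSymmetric(rho))
})

test_that("constant rows give NA rho, never 0", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  rho <- spearman_matrix(x)
  expect_true(all(is.na(rho["b", ])))
  expect_true(all(is.na(rho[, "b"])))
  expect_false(is.na(rho["a", "c"]))
  expect_error(spearman_matrix(x[, 1:2]), "3 samples")
})

test_that("null thresholds bracket zero, are seeded-deterministic and monotone in alpha", {
  sim <- generate_counts(synthetic_spec(n_samples = 24, n_taxa = 40,
                                        n_guilds = 0, noise_taxa_fraction = 0,
                                        n_env_params = 0, seed = 21))
  norm <- normalize_counts(prevalence_filter(sim$counts, 0.1))
  thr <- determine_thresholds(norm, n_permutations = 120, alpha = 0.02,
                              seed = 7)
  expect_lt(thr$rho_neg, 0)
  expect_gt(thr$rho_pos, 0)
  expect_identical(nrow(thr$null_quantiles), 120L)
  thr_again <- determine_thresholds(norm, n_permutations = 120, alpha = 0.02,
                                    seed = 7)
  expect_equal(thr$rho_pos, thr_again$rho_pos)
  expect_equal(thr$null_quantiles, thr_again$null_quantiles)
  # halving alpha can only push the positive threshold up
  thr_half <- determine_thresholds(norm, n_permutations = 120, alpha = 0.01,
                                   seed = 7)
  expect_gte(thr_half$rho_pos, thr$rho_pos)
  expect_lte(thr_half$rho_neg, thr$rho_neg)
  expect_error(determine_thresholds(norm, n_permutations = 50), "100")
  # degenerate all-constant data rejected
  flat <- as_norm(matrix(1, 4, 10))
  expect_error(determine_thresholds(flat, n_permutations = 100),
               "degenerate")
})

test_that("null thresholds on a 38-sample dataset are in a plausible range", {
  # sanity anchor only: dataset-specific thresholds on independent data with
  # the seasonal-dataset sample count land well inside (0, 1)
  sim <- generate_counts(synthetic_spec(n_samples = 38, n_taxa = 150,
                                        n_guilds = 0, noise_taxa_fraction = 0.2,
                                        n_env_params = 0, seed = 31))
  norm <- normalize_counts(prevalence_filter(sim$counts, 0.1))
  thr <- determine_thresholds(norm, n_permutations = 150, alpha = 0.01,
                              seed = 13)
  expect_gt(thr$rho_pos, 0.2)
  expect_lt(thr$rho_pos, 0.8)
})

test_that("consensus recovers duplicates, rejects unattainable thresholds", {
  set.seed(5)
  base <- matrix(stats::rnorm(80), 4, 20)
  x <- rbind(base, base[1, , drop = FALSE])  # duplicate of row 1
  rownames(x) <- c(sprintf("r%d", 1:4), "dup")
  colnames(x) <- sprintf("s%02d", 1:20)
  norm <- as_norm(x)
  thr <- determine_thresholds(norm, n_permutations = 100, alpha = 0.05,
                              seed = 2)
  net <- build_consensus(norm, thr, n_jitter = 40, seed = 3)
  expect_true("r1--dup" %in% paste(igraph::as_edgelist(net)[, 1],
                                   igraph::as_edgelist(net)[, 2], sep = "--") ||
              "dup--r1" %in% paste(igraph::as_edgelist(net)[, 1],
                                   igraph::as_edgelist(net)[, 2], sep = "--"))
  eid <- igraph::get_edge_ids(net, c("r1", "dup"))
  expect_equal(igraph::E(net)$rho[eid], 1)
  expect_equal(igraph::E(net)$persistence[eid], 1)
  # unattainable threshold -> empty network
  thr_hi <- thr
  thr_hi$rho_pos <- 1.01
  thr_hi$rho_neg <- -1.01
  empty <- build_consensus(norm, thr_hi, n_jitter = 10, seed = 3)
  expect_equal(igraph::vcount(empty), 0)
  expect_error(build_consensus(norm, thr, persistence_cutoff = 0), "persistence")
})

test_that("consensus edge set shrinks as the persistence cutoff rises", {
  sim <- generate_counts(synthetic_spec(n_samples = 24, n_taxa = 40,
                                        n_guilds = 2, guild_size = 6,
                                        within_guild_rho = 0.8, seed = 17))
  norm <- normalize_counts(prevalence_filter(sim$counts, 0.1))
  thr <- determine_thresholds(norm, n_permutations = 100, seed = 4)
  prev_edges <- Inf
  for (pc in c(0.25, 0.5, 0.75, 0.99)) {
    net <- build_consensus(norm, thr, n_jitter = 40,
                           persistence_cutoff = pc, seed = 9)
    expect_lte(igraph::ecount(net), prev_edges)
    prev_edges <- igraph::ecount(net)
  }
})

test_that("planted guild edges are recovered and co-exclusion is representable", {
  sim <- generate_counts(synthetic_spec(n_samples = 36, n_taxa = 60,
                                        n_guilds = 2, guild_size = 8,
                                        within_guild_rho = 0.95,
                                        noise_taxa_fraction = 0.2, seed = 23))
  norm <- append_env(normalize_counts(prevalence_filter(sim$counts, 0.1)),
                     sim$env)
  thr <- determine_thresholds(norm, n_permutations = 150, seed = 6)
  net <- build_consensus(norm, thr, n_jitter = 50, seed = 7)
  planted <- apply(sim$truth$planted_edges, 1, paste, collapse = "--")
  recovered <- edge_keys(net)
  expect_gte(mean(planted %in% recovered), 0.9)
  # negative-threshold edges are representable: force a co-exclusion pair
  x <- rbind(up = as.numeric(1:20) + stats::rnorm(20, 0, 0.1),
             down = -as.numeric(1:20) + stats::rnorm(20, 0, 0.1))
  colnames(x) <- sprintf("s%02d", 1:20)
  norm2 <- as_norm(rbind(x, matrix(stats::rnorm(100), 5, 20,
                                   dimnames = list(sprintf("n%d", 1:5),
                                                   colnames(x)))))
  thr2 <- determine_thresholds(norm2, n_permutations = 100, alpha = 0.05,
                               seed = 8)
  net2 <- build_consensus(norm2, thr2, n_jitter = 30, seed = 9)
  eid <- igraph::get_edge_ids(net2, c("up", "down"))
  expect_gt(eid, 0)
  expect_identical(igraph::E(net2)$sign[eid], -1L)
})
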