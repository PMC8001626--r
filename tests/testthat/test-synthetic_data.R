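test_that("generated counts respect dimensions, depths and determinism", {
  spec <- synthetic_spec(n_samples = 20, n_taxa = 60, n_guilds = 3,
                         guild_size = 5, seed = 11)
  sim <- generate_counts(spec)
  expect_identical(dim(sim$counts), c(60L, 20L))
  # multinomial conservation: column sums equal the drawn depths exactly
  expect_identical(unname(colSums(sim$counts)), as.numeric(sim$depths))
  expect_true(all(sim$counts >= 0))
  # bit-identical under the same spec
  sim2 <- generate_counts(spec)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$env, sim2$env)
  expect_identical(sim$latent, sim2$latent)
  # different seed changes the data
  sim3 <- generate_counts(synthetic_spec(n_samples = 20, n_taxa = 60,
                                         n_guilds = 3, guild_size = 5,
                                         seed = 12))
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("perfect copula makes guild members rank-identical", {
  spec <- synthetic_spec(n_samples = 15, n_taxa = 10, n_guilds = 2,
                         guild_size = 5, within_guild_rho = 1,
                         depth_cv = 0, noise_taxa_fraction = 0, seed = 3)
  sim <- generate_counts(spec)
  for (g in 1:2) {
    members <- names(which(sim$truth$guild_membership == g))
    ranks <- apply(sim$latent[members, ], 1L, rank)
    expect_true(all(apply(ranks, 1L, function(r) length(unique(r)) == 1)))
  }
  expect_true(all(colSums(sim$counts) == round(spec$depth_mean)))
})

test_that("planted within-guild rank correlation matches the requested level", {
  sim <- generate_counts(synthetic_spec(n_samples = 36, n_taxa = 60,
                                        n_guilds = 4, guild_size = 10,
                                        within_guild_rho = 0.9,
                                        noise_taxa_fraction = 0, seed = 1))
  rhos <- c()
  for (g in 1:4) {
    members <- names(which(sim$truth$guild_membership == g))
    cc <- stats::cor(t(sim$latent[members, ]), method = "spearman")
    rhos <- c(rhos, cc[upper.tri(cc)])
  }
  expect_gt(mean(rhos), 0.6)
  expect_lt(mean(rhos), 0.95)
})

test_that("without guilds all taxa are mutually independent", {
  sim <- generate_counts(synthetic_spec(n_samples = 30, n_taxa = 80,
                                        n_guilds = 0, guild_size = 0,
                                        noise_taxa_fraction = 0,
                                        n_env_params = 0, seed = 5))
  cc <- stats::cor(t(sim$latent), method = "spearman")
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.02)
  expect_identical(nrow(sim$truth$planted_edges), 0L)
})

test_that("with zero planted correlation, within- and between-guild pairs are alike", {
  sim <- generate_counts(synthetic_spec(n_samples = 40, n_taxa = 60,
                                        n_guilds = 4, guild_size = 10,
                                        within_guild_rho = 0,
                                        noise_taxa_fraction = 0, seed = 8))
  cc <- stats::cor(t(sim$latent), method = "spearman")
  gm <- sim$truth$guild_membership
  same <- outer(gm, gm, function(a, b) !is.na(a) & !is.na(b) & a == b)
  ut <- upper.tri(cc)
  frac_within <- mean(abs(cc[ut & same]) > 0.6)
  frac_between <- mean(abs(cc[ut & !same]) > 0.6)
  # both should be tiny and statistically indistinguishable
  expect_lt(frac_within, 0.02)
  expect_lt(abs(frac_within - frac_between), 0.02)
})

test_that("planted edges are exactly the within-guild pairs, guilds disjoint", {
  sim <- generate_counts(synthetic_spec(n_samples = 20, n_taxa = 30,
                                        n_guilds = 3, guild_size = 4, seed = 2))
  gm <- sim$truth$guild_membership
  expect_identical(sum(!is.na(gm)), 12L)
  pe <- sim$truth$planted_edges
  expect_identical(nrow(pe), 18L)
  same_guild <- apply(pe, 1, function(r) gm[r[1]] == gm[r[2]])
  expect_true(all(same_guild))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(synthetic_spec(n_guilds = 5, guild_size = 10, n_taxa = 20),
               "exceeds n_taxa")
  expect_error(synthetic_spec(within_guild_rho = 1.2), "within_guild_rho")
  expect_error(synthetic_spec(depth_mean = 0), "depth_mean")
  expect_error(synthetic_spec(n_samples = 0), "positive")
})

test_that("similarity generator plants recoverable clusters", {
  sm <- generate_similarity_matrix(4, 2, 98, 90, seed = 0)
  expect_true(isSymmetric(unname(sm$identity)))
  expect_true(all(diag(sm$identity) == 100))
  nsc <- build_nscs(sm, threshold = 97)
  expect_identical(length(nsc$nsc_ids), 2L)
  recovered <- unname(lapply(split(names(nsc$member_map), nsc$member_map), sort))
  planted <- unname(lapply(split(names(sm$truth), sm$truth), sort))
  expect_setequal(recovered, planted)

  one <- generate_similarity_matrix(1, 1, 99, 50, seed = 0)
  expect_identical(dim(one$identity), c(1L, 1L))
  expect_identical(unname(one$identity[1, 1]), 100)

  expect_error(generate_similarity_matrix(3, 5, 98, 90), "exceed")
  expect_error(generate_similarity_matrix(3, 2, 90, 95), "exceed")
})
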