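#' Specification for a synthetic metabarcoding dataset
#'
#' Describes a taxa-by-sample count table with planted co-occurring guilds,
#' environmental parameters linked to some guilds, heavy-tailed taxon
#' abundances, sparse noise taxa and variable sequencing depth. The defaults
#' emulate a biweekly lake time series: roughly three dozen samples per
#' seasonal dataset, a few hundred sequence clusters of which a planted subset
#' forms guild structure, and a handful of continuous environmental
#' parameters.
#'
#' Guild members receive rank-correlated abundance trajectories through a
#' Gaussian copula: `within_guild_rho` is the target *Spearman* correlation
#' between members, converted internally to the latent Pearson scale
#' (`2*sin(pi*rho/6)`) so the planted rank correlation is exact in
#' expectation. Sequencing depth per sample is log-normal with mean
#' `depth_mean` and coefficient of variation `depth_cv`; counts are a
#' multinomial resample of the latent relative abundances at that depth.
#'
#' @param n_samples number of samples (columns).
#' @param n_taxa total number of taxa (rows), including guild members,
#'   sparse noise taxa and independent background taxa.
#' @param n_guilds number of planted guilds (0 for fully independent data).
#' @param guild_size taxa per guild; `n_guilds * guild_size` must not
#'   exceed `n_taxa`.
#' @param within_guild_rho target Spearman correlation between members of the
#'   same guild, in `[0, 1]`.
#' @param n_env_params number of environmental parameters.
#' @param env_linked_guilds integer vector of guild indices that drive an
#'   environmental parameter (one parameter per listed guild; remaining
#'   parameters are independent noise).
#' @param depth_mean expected reads per sample.
#' @param depth_cv coefficient of variation of the per-sample depth
#'   (0 gives every sample exactly `depth_mean` reads).
#' @param noise_taxa_fraction fraction of `n_taxa` that are sparse noise taxa,
#'   present in only a few samples (they exercise the downstream prevalence
#'   filter).
#' @param seasonal_amplitude strength in `[0, 1)` of a smooth seasonal cycle
#'   added to each guild's latent signal; sample dates are biweekly.
#' @param abundance_sdlog between-taxon spread of baseline log abundance
#'   (heavy-tailed taxon sizes).
#' @param noise_presence_prob per-sample presence probability of a sparse
#'   noise taxon.
#' @param seed integer seed; together with the other fields it fully
#'   determines the generated dataset.
#'
#' @return an object of class `"synthetic_spec"` (a validated list).
#' @seealso [generate_counts()]
#' @export
synthetic_spec <- function(n_samples = 36, n_taxa = 200, n_guilds = 4,
                           guild_size = 10, within_guild_rho = 0.9,
                           n_env_params = 6,
                           env_linked_guilds = seq_len(min(n_guilds, n_env_params)),
                           depth_mean = 5e4, depth_cv = 0.3,
                           noise_taxa_fraction = 0.3,
                           seasonal_amplitude = 0.6,
                           abundance_sdlog = 1.2,
                           noise_presence_prob = 0.15,
                           seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
               n_guilds = as.integer(n_guilds), guild_size = as.integer(guild_size),
               within_guild_rho = within_guild_rho,
               n_env_params = as.integer(n_env_params),
               env_linked_guilds = as.integer(env_linked_guilds),
               depth_mean = depth_mean, depth_cv = depth_cv,
               noise_taxa_fraction = noise_taxa_fraction,
               seasonal_amplitude = seasonal_amplitude,
               abundance_sdlog = abundance_sdlog,
               noise_presence_prob = noise_presence_prob,
               seed = as.integer(seed))
  if (spec$n_samples < 1 || spec$n_taxa < 1)
    stop("n_samples and n_taxa must be positive")
  if (spec$n_guilds < 0 || (spec$n_guilds > 0 && spec$guild_size < 1))
    stop("n_guilds must be >= 0 and guild_size positive when guilds are planted")
  if (spec$within_guild_rho < 0 || spec$within_guild_rho > 1)
    stop("within_guild_rho must lie in [0, 1]")
  if (spec$n_guilds * spec$guild_size > spec$n_taxa)
    stop("n_guilds * guild_size exceeds n_taxa")
  if (spec$depth_mean <= 0) stop("depth_mean must be positive")
  if (spec$depth_cv < 0) stop("depth_cv must be non-negative")
  if (spec$noise_taxa_fraction < 0 || spec$noise_taxa_fraction > 1)
    stop("noise_taxa_fraction must lie in [0, 1]")
  n_guild_taxa <- spec$n_guilds * spec$guild_size
  n_noise <- round(spec$noise_taxa_fraction * spec$n_taxa)
  if (n_guild_taxa + n_noise > spec$n_taxa)
    stop("guild taxa plus noise taxa exceed n_taxa; lower noise_taxa_fraction")
  if (length(spec$env_linked_guilds) &&
      (spec$n_guilds == 0 || any(spec$env_linked_guilds < 1) ||
       any(spec$env_linked_guilds > spec$n_guilds)))
    spec$env_linked_guilds <- integer(0)
  if (length(spec$env_linked_guilds) > spec$n_env_params)
    spec$env_linked_guilds <- spec$env_linked_guilds[seq_len(spec$n_env_params)]
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic count table with planted guild structure
#'
#' Draws a latent log-normal abundance matrix in which members of the same
#' guild are rank-correlated through a Gaussian copula, adds independent
#' background taxa and sparse noise taxa, then resamples each sample
#' multinomially to a log-normally distributed sequencing depth.
#' Environmental parameters are monotone transforms of the latent guild
#' signals plus measurement noise. Sample ids carry biweekly dates and a
#' cold/warm season label (October-April vs May-September).
#'
#' @param spec a [synthetic_spec()] object.
#' @return a list of class `"synthetic_dataset"` with elements
#'   \describe{
#'     \item{counts}{integer taxa-by-sample count matrix}
#'     \item{env}{numeric parameter-by-sample matrix}
#'     \item{truth}{ground truth: `guild_membership` (named integer vector,
#'       `NA` for non-guild taxa), `planted_edges` (two-column character
#'       matrix of within-guild pairs), `env_links` (data frame of
#'       parameter/guild links)}
#'     \item{latent}{the latent (pre-resampling) abundance matrix}
#'     \item{depths}{drawn per-sample read depths}
#'     \item{seasons}{named factor, `"cold"`/`"warm"` per sample}
#'     \item{spec}{the input spec}
#'   }
#' @examples
#' sim <- generate_counts(synthetic_spec(n_samples = 12, n_taxa = 30,
#'                                       n_guilds = 2, guild_size = 5, seed = 42))
#' dim(sim$counts)
#' table(sim$truth$guild_membership, useNA = "ifany")
#' @export
generate_counts <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_taxa
  taxon_ids <- sprintf("t%04d", seq_len(m))
  # biweekly sampling dates -> season labels
  dates <- as.Date("2014-01-07") + 14 * (seq_len(n) - 1)
  months <- as.integer(format(dates, "%m"))
  seasons <- factor(ifelse(months >= 5 & months <= 9, "warm", "cold"),
                    levels = c("cold", "warm"))
  sample_ids <- sprintf("s%02d_%s", seq_len(n), format(dates, "%Y%m%d"))
  names(seasons) <- sample_ids

  n_guild_taxa <- spec$n_guilds * spec$guild_size
  n_noise <- round(spec$noise_taxa_fraction * m)
  guild_membership <- rep(NA_integer_, m)
  if (n_guild_taxa > 0)
    guild_membership[seq_len(n_guild_taxa)] <- rep(seq_len(spec$n_guilds),
                                                   each = spec$guild_size)
  names(guild_membership) <- taxon_ids
  is_noise <- seq_len(m) > (m - n_noise)

  # latent Pearson correlation that yields the requested Spearman correlation
  # under a Gaussian copula
  r_latent <- 2 * sin(pi * spec$within_guild_rho / 6)

  # Per-guild latent signal: a seasonal cosine (guild-specific phase) blended
  # with temporally smoothed noise. The signals are then orthogonalized
  # against the intercept and against each other (QR), so guilds are exactly
  # uncorrelated at the latent level and the planted truth -- edges only
  # within guilds -- is self-consistent. Requires n_samples > n_guilds.
  t_frac <- as.numeric(dates - dates[1]) / 365.25
  z <- matrix(stats::rnorm(m * n), m, n)
  guild_signals <- NULL
  if (spec$n_guilds > 0) {
    if (n <= spec$n_guilds)
      stop("n_samples must exceed n_guilds to plant independent guild signals")
    amp <- spec$seasonal_amplitude
    raw <- matrix(NA_real_, n, spec$n_guilds)
    for (g in seq_len(spec$n_guilds)) {
      phase <- stats::runif(1, 0, 2 * pi)
      seasonal <- cos(2 * pi * t_frac + phase)
      rough <- stats::rnorm(n)
      smooth <- as.numeric(stats::filter(rough, rep(1 / 3, 3), sides = 2))
      smooth[is.na(smooth)] <- rough[is.na(smooth)]
      raw[, g] <- sqrt(amp) * seasonal / stats::sd(seasonal) +
        sqrt(1 - amp) * smooth / stats::sd(smooth)
    }
    qd <- qr(cbind(1, raw))
    ortho <- qr.Q(qd)[, 1 + seq_len(spec$n_guilds), drop = FALSE]
    guild_signals <- apply(ortho, 2L, function(v) v / stats::sd(v))
    for (g in seq_len(spec$n_guilds)) {
      zg <- guild_signals[, g]
      members <- which(guild_membership == g)
      eps <- matrix(stats::rnorm(length(members) * n), length(members), n)
      z[members, ] <- sqrt(r_latent) * matrix(zg, length(members), n, byrow = TRUE) +
        sqrt(1 - r_latent) * eps
    }
  }

  # heavy-tailed baseline abundances; latent abundance is a monotone
  # (exponential) transform of the copula variable, preserving ranks
  base_meanlog <- stats::rnorm(m, mean = log(100), sd = spec$abundance_sdlog)
  latent <- exp(base_meanlog + z)
  if (any(is_noise)) {
    present <- matrix(stats::runif(sum(is_noise) * n) < spec$noise_presence_prob,
                      sum(is_noise), n)
    latent[is_noise, ][!present] <- 0
  }
  dimnames(latent) <- list(taxon_ids, sample_ids)

  # per-sample depths, then multinomial resampling of relative abundances
  if (spec$depth_cv > 0) {
    sdl <- sqrt(log(1 + spec$depth_cv^2))
    depths <- round(stats::rlnorm(n, meanlog = log(spec$depth_mean) - sdl^2 / 2,
                                  sdlog = sdl))
    depths <- pmax(depths, 1)
  } else {
    depths <- rep(round(spec$depth_mean), n)
  }
  names(depths) <- sample_ids
  counts <- matrix(0L, m, n, dimnames = dimnames(latent))
  for (j in seq_len(n)) {
    p <- latent[, j]
    if (sum(p) == 0) p <- rep(1, m)
    counts[, j] <- stats::rmultinom(1, size = depths[j], prob = p / sum(p))[, 1]
  }
  storage.mode(counts) <- "integer"

  # environmental parameters: monotone transforms of linked guild signals
  env <- matrix(NA_real_, spec$n_env_params, n,
                dimnames = list(if (spec$n_env_params > 0)
                  sprintf("env%02d", seq_len(spec$n_env_params)) else NULL,
                  sample_ids))
  env_links <- data.frame(param = character(0), guild = integer(0))
  if (spec$n_env_params > 0) {
    for (k in seq_len(spec$n_env_params)) {
      if (k <= length(spec$env_linked_guilds)) {
        g <- spec$env_linked_guilds[k]
        sig <- guild_signals[, g]
        env[k, ] <- 10 + 4 * (sig + 0.5 * stats::rnorm(n))
        env_links <- rbind(env_links,
                           data.frame(param = rownames(env)[k], guild = g))
      } else {
        env[k, ] <- 10 + 4 * stats::rnorm(n)
      }
    }
  }

  planted_edges <- planted_edge_set(guild_membership)
  structure(list(counts = counts, env = env,
                 truth = list(guild_membership = guild_membership,
                              planted_edges = planted_edges,
                              env_links = env_links),
                 latent = latent, depths = depths, seasons = seasons,
                 spec = spec),
            class = "synthetic_dataset")
}

# all unordered within-guild taxon pairs, as a two-column character matrix
# with each row sorted; canonical order
planted_edge_set <- function(guild_membership) {
  out <- NULL
  for (g in unique(stats::na.omit(guild_membership))) {
    members <- sort(names(guild_membership)[!is.na(guild_membership) &
                                              guild_membership == g])
    if (length(members) >= 2) {
      pairs <- t(utils::combn(members, 2))
      out <- rbind(out, pairs)
    }
  }
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("a", "b")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Generate a pairwise percent-identity matrix with planted clusters
#'
#' Builds a symmetric percent-identity matrix in which sequence pairs from the
#' same planted cluster score at least `within_identity` and pairs from
#' different clusters at most `between_identity`, so that thresholding between
#' the two values recovers the planted clusters exactly as connected
#' components.
#'
#' @param n_sequences number of sequences.
#' @param n_true_clusters number of planted clusters (must not exceed
#'   `n_sequences`).
#' @param within_identity minimum identity (percent) within a cluster.
#' @param between_identity maximum identity (percent) between clusters; must
#'   be below `within_identity`.
#' @param seed integer seed.
#' @return a list of class `"similarity_matrix"` with `ids` and a symmetric
#'   `identity` matrix (diagonal 100), plus the planted `truth` assignment.
#' @export
generate_similarity_matrix <- function(n_sequences, n_true_clusters,
                                       within_identity, between_identity,
                                       seed = 1L) {
  if (n_sequences < 1) stop("n_sequences must be positive")
  if (n_true_clusters > n_sequences)
    stop("n_true_clusters cannot exceed n_sequences")
  if (n_true_clusters < 1) stop("n_true_clusters must be positive")
  if (within_identity <= between_identity)
    stop("within_identity must exceed between_identity")
  set.seed(seed)
  ids <- sprintf("seq%04d", seq_len(n_sequences))
  # every cluster gets at least one member; remainder assigned at random
  assignment <- c(seq_len(n_true_clusters),
                  sample.int(n_true_clusters, n_sequences - n_true_clusters,
                             replace = TRUE))[seq_len(n_sequences)]
  identity <- matrix(NA_real_, n_sequences, n_sequences,
                     dimnames = list(ids, ids))
  for (i in seq_len(n_sequences)) {
    for (j in seq_len(n_sequences)) {
      if (j <= i) next
      same <- assignment[i] == assignment[j]
      identity[i, j] <- if (same)
        stats::runif(1, within_identity, 100)
      else
        stats::runif(1, max(0, between_identity - 10), between_identity)
      identity[j, i] <- identity[i, j]
    }
  }
  diag(identity) <- 100
  names(assignment) <- ids
  structure(list(ids = ids, identity = identity, truth = assignment),
            class = "similarity_matrix")
}
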