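#' Default pipeline configuration
#'
#' Returns the full list of pipeline settings with their defaults; any
#' supplied value overrides the default. Every randomized stage derives its
#' own seed deterministically from the master `seed` and the stage name, so
#' a run is reproducible from the config alone. Per-stage overrides may be
#' given in `stage_seeds` (a named list, e.g.
#' `list("thresholds/cold" = 99L)`).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    counts = NULL,            # path to counts TSV, or a matrix
    env = NULL,               # path to env TSV, or a matrix (optional)
    similarity = NULL,        # path to similarity TSV or object (optional)
    groups = NULL,            # named list: group -> sample ids, or path to
                              # two-column TSV (sample, season); NULL = one
                              # group "all"
    nsc_threshold = 97,       # percent identity for second-level clustering
    min_total = 3,            # minimum NSC total reads
    min_prevalence = 0.10,    # minimum fraction of samples present
    pseudocount = 1,
    normalization_variant = "log_depth",
    n_permutations = 1000,    # null-model permutations
    alpha = 0.01,             # tolerated expected false-edge fraction
    jitter_scale = 1e-6,
    n_jitter = 100,           # consensus replicates
    persistence_cutoff = 0.5,
    modularity_seed = 1L,
    n_boot = 10000,           # keystone bootstrap resamples
    keystone_ci = 0.95,
    n_removals = 50,          # attack-curve length (capped at network size)
    loss_levels = c(0.5, 0.95),
    seed = 1L,                # master seed
    stage_seeds = list(),
    out_dir = NULL)
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  class(defaults) <- c("pipeline_config", "list")
  defaults
}

config_seed <- function(config, stage) {
  override <- config$stage_seeds[[stage]]
  if (!is.null(override)) as.integer(override)
  else stage_seed(config$seed, stage)
}

#' Run the full co-occurrence network pipeline
#'
#' Orchestrates, per sample group (typically seasonal datasets): optional
#' second-level clustering of the count table on a similarity matrix,
#' minimum-abundance and prevalence filtering, depth-aware log
#' normalization, appending environmental parameters, permutation-null
#' Spearman thresholds, consensus network construction, topology report,
#' keystone detection, and the cascading-attack robustness curve. All
#' artifacts are written under `config$out_dir` together with a run manifest
#' recording the configuration, its hash and every derived stage seed.
#'
#' @param config a [pipeline_config()], a plain named list of overrides, or
#'   the path to a YAML file of overrides.
#' @return (invisibly) a named list of per-group results, each with elements
#'   `norm`, `thresholds`, `network`, `topology`, `keystones`, `attack`,
#'   `attack_summary`; plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$counts)) stop("config$counts is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- if (is.character(config$counts)) read_count_table(config$counts)
            else config$counts
  assert_count_table(counts)
  env <- if (is.character(config$env)) read_env_table(config$env)
         else config$env
  if (!is.null(env)) {
    missing <- setdiff(colnames(counts), colnames(env))
    if (length(missing))
      stop("samples absent from environmental table: ",
           paste(missing, collapse = ", "))
  }

  if (!is.null(config$similarity)) {
    sim <- if (is.character(config$similarity))
      read_similarity_matrix(config$similarity) else config$similarity
    assignment <- build_nscs(sim, threshold = config$nsc_threshold)
    counts <- aggregate_counts(counts, assignment)
  }
  counts <- filter_min_abundance(counts, min_total = config$min_total)

  groups <- config$groups
  if (is.character(groups) && length(groups) == 1) {
    gdf <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- split(gdf[[1]], gdf[[2]])
  }
  if (is.null(groups)) groups <- list(all = colnames(counts))
  bad <- setdiff(unlist(groups), colnames(counts))
  if (length(bad))
    stop("group sample ids not found in count table: ",
         paste(bad, collapse = ", "))

  results <- list()
  seeds_used <- list()
  for (grp in names(groups)) {
    gdir <- file.path(config$out_dir, grp)
    dir.create(gdir, showWarnings = FALSE)
    sub <- counts[, groups[[grp]], drop = FALSE]
    sub <- prevalence_filter(sub, min_prevalence = config$min_prevalence)
    write_table_tsv(sub, file.path(gdir, "filtered_counts.tsv"))
    norm <- normalize_counts(sub, pseudocount = config$pseudocount,
                             variant = config$normalization_variant)
    if (!is.null(env))
      norm <- append_env(norm, env[, groups[[grp]], drop = FALSE])

    s_thr <- config_seed(config, paste0("thresholds/", grp))
    s_con <- config_seed(config, paste0("consensus/", grp))
    s_key <- config_seed(config, paste0("keystones/", grp))
    seeds_used[[grp]] <- list(thresholds = s_thr, consensus = s_con,
                              keystones = s_key)
    thresholds <- determine_thresholds(norm,
                                       n_permutations = config$n_permutations,
                                       alpha = config$alpha, seed = s_thr,
                                       jitter_scale = config$jitter_scale)
    jsonlite::write_json(
      list(rho_pos = thresholds$rho_pos, rho_neg = thresholds$rho_neg,
           n_permutations = thresholds$n_permutations,
           alpha = thresholds$alpha, seed = thresholds$seed,
           jitter_scale = thresholds$jitter_scale,
           threshold_rule = "mean per-permutation (1-alpha) null quantile"),
      file.path(gdir, "thresholds.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    net <- build_consensus(norm, thresholds, n_jitter = config$n_jitter,
                           persistence_cutoff = config$persistence_cutoff,
                           seed = s_con)
    write_graphml(net, file.path(gdir, "network.graphml"))
    write_edge_list(net, file.path(gdir, "edges.tsv"))

    if (igraph::vcount(net) > 0) {
      topo <- compute_topology(net, modularity_seed = config$modularity_seed)
      jsonlite::write_json(unclass(topo), file.path(gdir, "topology.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_topology_table(topo, file.path(gdir, "topology.tsv"))
      keys <- if (igraph::vcount(net) >= 3)
        find_key_nodes(net, n_boot = config$n_boot, ci = config$keystone_ci,
                       seed = s_key) else NULL
      if (!is.null(keys))
        utils::write.table(keys, file.path(gdir, "keystones.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      nrem <- min(config$n_removals, igraph::vcount(net))
      attack <- cascading_attack(net, n_removals = nrem)
      utils::write.csv(attack, file.path(gdir, "attack.csv"),
                       row.names = FALSE)
      summ <- attack_summary(attack, loss_levels = config$loss_levels)
      jsonlite::write_json(as.list(summ), file.path(gdir, "attack_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
    } else {
      topo <- NULL; keys <- NULL; attack <- NULL; summ <- NULL
    }
    results[[grp]] <- list(norm = norm, thresholds = thresholds,
                           network = net, topology = topo, keystones = keys,
                           attack = attack, attack_summary = summ)
  }

  cfg_for_hash <- config
  # the output location does not influence any result; keep it out of the
  # reproducibility fingerprint so reruns elsewhere compare byte-identical
  cfg_for_hash$out_dir <- NULL
  cfg_for_hash$counts <- if (is.character(config$counts)) config$counts
                         else fnv1a_hash(paste(config$counts, collapse = ","))
  cfg_for_hash$env <- if (is.character(config$env) || is.null(config$env))
                        config$env
                      else fnv1a_hash(paste(config$env, collapse = ","))
  cfg_for_hash$similarity <- if (is.character(config$similarity) ||
                                 is.null(config$similarity)) config$similarity
                             else "object"
  cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA, null = "null", pretty = TRUE)
  manifest <- list(
    package = "coocnet",
    version = as.character(utils::packageVersion("coocnet")),
    master_seed = config$seed,
    config_hash = fnv1a_hash(as.character(cfg_json)),
    stage_seeds = seeds_used,
    groups = lapply(results, function(r)
      list(n_nodes = if (is.null(r$topology)) 0L else r$topology$n_nodes,
           n_edges = if (is.null(r$topology)) 0L else r$topology$n_edges,
           rho_pos = r$thresholds$rho_pos,
           rho_neg = r$thresholds$rho_neg)),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}

# Table-2-shaped one-column report
write_topology_table <- function(topo, path) {
  rows <- data.frame(
    property = c("Edges (co-occurrences)", "Nodes", "Nodes of environmental parameters",
                 "Average degree", "Average path length",
                 "Connected components (larger than 3 nodes)",
                 "Connected components (pairs)", "Connected components (total)",
                 "Density", "Diameter", "Modularity", "Transitivity"),
    value = c(topo$n_edges, topo$n_nodes, topo$n_env_nodes,
              round(topo$average_degree, 2), round(topo$average_path_length, 2),
              topo$components_gt3, topo$components_pairs, topo$components_total,
              round(topo$density, 3), topo$diameter,
              round(topo$modularity, 2), round(topo$transitivity, 2)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
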