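#' Remove taxa occurring in too few samples
#'
#' Retains rows with nonzero counts in at least `ceiling(min_prevalence *
#' n_samples)` samples, i.e. rows present in strictly less than the requested
#' fraction of samples are removed. With the default 10% and 38 samples, a
#' taxon present in 3 samples (7.9%) is dropped and one present in 4 (10.5%)
#' is kept.
#'
#' @param counts taxa-by-sample integer matrix.
#' @param min_prevalence minimum fraction of samples, in `[0, 1]`.
#' @return the filtered count matrix (row order preserved).
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.10) {
  assert_count_table(counts)
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must lie in [0, 1]")
  need <- ceiling(min_prevalence * ncol(counts))
  counts[rowSums(counts > 0) >= need, , drop = FALSE]
}

#' Depth-aware log normalization
#'
#' Log-ratio-style transform for compositional read counts:
#' \deqn{v_{ij} = \log(c_{ij} + 1) - \log d_j + \log \tilde d}
#' where \eqn{d_j} is the total reads of sample \eqn{j} and \eqn{\tilde d}
#' the median depth over samples. This corrects each sample for its
#' sequencing depth while re-centering on the dataset's expected depth; a
#' zero count in a median-depth sample maps to exactly 0. Downstream
#' statistics are Spearman correlations over samples, which depend only on
#' within-row ranks, so the transform mainly standardizes reporting; an
#' alternative `variant = "rank"` replaces each row by its ranks.
#'
#' @param counts taxa-by-sample integer matrix (already filtered).
#' @param pseudocount value added to counts before the log (default 1).
#' @param variant `"log_depth"` (default) or `"rank"`.
#' @return an object of class `"normalized_table"`: list with `values`
#'   (numeric matrix), `is_env` (named logical, all `FALSE` here),
#'   `row_totals` (total reads per row, used as node abundance downstream)
#'   and `variant`.
#' @export
normalize_counts <- function(counts, pseudocount = 1, variant = c("log_depth", "rank")) {
  assert_count_table(counts)
  variant <- match.arg(variant)
  depths <- colSums(counts)
  if (any(depths == 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[depths == 0], collapse = ", "))
  values <- switch(variant,
    log_depth = {
      med <- stats::median(depths)
      log(counts + pseudocount) +
        matrix(log(med) - log(depths), nrow(counts), ncol(counts), byrow = TRUE)
    },
    rank = row_ranks(counts))
  dimnames(values) <- dimnames(counts)
  is_env <- stats::setNames(rep(FALSE, nrow(counts)), rownames(counts))
  structure(list(values = values, is_env = is_env,
                 row_totals = rowSums(counts), variant = variant),
            class = "normalized_table")
}

#' Append environmental parameters as co-analyzed rows
#'
#' Environmental parameter rows enter the correlation analysis exactly like
#' taxa but are never log-transformed (rank correlation is invariant to
#' monotone transforms, and parameters such as winter temperatures can be
#' negative). Samples are aligned by id; parameters with any missing value in
#' the retained samples are dropped with a warning.
#'
#' @param norm a `"normalized_table"` from [normalize_counts()].
#' @param env parameter-by-sample numeric matrix; column names must overlap
#'   the normalized table's samples.
#' @return the normalized table with parameter rows appended
#'   (`is_env = TRUE`).
#' @export
append_env <- function(norm, env) {
  stopifnot(inherits(norm, "normalized_table"))
  if (is.null(env) || nrow(env) == 0) return(norm)
  if (is.null(colnames(env))) stop("environmental table must have sample ids")
  samples <- colnames(norm$values)
  if (!any(samples %in% colnames(env)))
    stop("no overlapping samples between count and environmental tables")
  missing_samples <- setdiff(samples, colnames(env))
  if (length(missing_samples))
    stop("environmental table lacks samples: ",
         paste(missing_samples, collapse = ", "))
  env <- env[, samples, drop = FALSE]
  complete <- !apply(env, 1L, anyNA)
  if (any(!complete))
    warning("dropping environmental parameter(s) with missing values: ",
            paste(rownames(env)[!complete], collapse = ", "))
  env <- env[complete, , drop = FALSE]
  if (any(rownames(env) %in% rownames(norm$values)))
    stop("environmental parameter ids clash with taxon ids")
  norm$values <- rbind(norm$values, env)
  norm$is_env <- c(norm$is_env,
                   stats::setNames(rep(TRUE, nrow(env)), rownames(env)))
  norm$row_totals <- c(norm$row_totals,
                       stats::setNames(rep(NA_real_, nrow(env)), rownames(env)))
  norm
}
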