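# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count table must be a numeric matrix (taxa in rows, samples in columns)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have row (taxon) and column (sample) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids in count table")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in count table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count table must contain non-negative integers")
  invisible(counts)
}

# tie-averaged ranks, row-wise; returns matrix of the same shape
row_ranks <- function(x) {
  t(apply(x, 1L, rank))
}

# per-row jitter amplitude: scale * IQR of the row (0 for constant rows,
# which therefore stay constant and can never form edges)
jitter_amplitudes <- function(x, scale) {
  scale * apply(x, 1L, stats::IQR)
}

# deterministic per-stage seed derived from a master seed and a stage label;
# kept inside the 32-bit integer range
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 2654435.0 + h) %% 2147483647)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits;
# used to fingerprint configurations in run manifests. Arithmetic is done on
# 16-bit halves to stay inside R's 32-bit signed integers.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    # (h * prime) mod 2^32, split so every intermediate stays exact in doubles
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
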