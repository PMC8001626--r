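---
title: "Inferring and stress-testing plankton co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and stress-testing plankton co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The problem

Metabarcoding time series of plankton communities yield taxa-by-sample read
count tables. Two taxa that are ecologically associated — through shared
niches, trophic links, or parasitism — tend to show correlated abundance
trajectories across the series. A co-occurrence network makes this operational:
nodes are sequence clusters (and optionally environmental parameters), and an
edge is a statistically significant rank correlation between two abundance
profiles. Graph-theoretic descriptors of the network (density, transitivity,
path lengths, modularity), keystone-node calls, and simulated extinction
cascades then characterize how tightly and how robustly the community is
wired, e.g. when contrasting seasonal datasets under a warming regime.

This vignette documents the model and the concrete numerical choices made at
each stage; it is the design record for the package.

## Input units: network sequence clusters

First-level sequence clustering (e.g. single-linkage swarm clustering of
amplicons) tends to leave several clusters per biological species. Because
those fragments co-vary trivially, they would inflate nodes and edges with
false-positive associations. `build_nscs()` therefore agglomerates first-level
clusters into *network sequence clusters* (NSCs): nodes of a similarity graph
with an edge wherever pairwise identity is at or above a threshold (default
97%), taking connected components so linkage is transitive. The threshold
comparison is **inclusive** (`>= 97`); strictness was a genuinely open choice
and the value is a plain argument. NSC labels are canonical (lexicographically
smallest member), making the assignment invariant to input order.
`aggregate_counts()` sums member rows, conserving reads; `filter_min_abundance()`
then drops NSCs with fewer than 3 total reads (a row with exactly 3 survives).
Retention decisions that depend on external databases (taxonomy matching) are
out of scope; `filter_allowlist()` accepts a precomputed keep-list instead.

## Filtering and normalization

`prevalence_filter()` removes taxa present in fewer than
`ceiling(0.10 * n_samples)` samples — the strict reading of "less than 10% of
samples", so with 38 samples presence in 4 samples survives and 3 does not.

`normalize_counts()` applies a depth-aware log transform,

$$v_{ij} = \log(c_{ij} + 1) - \log d_j + \log \tilde d,$$

with $d_j$ the read depth of sample $j$ and $\tilde d$ the median depth. The
pseudo-count handles zeros; re-centering on the median depth makes the values
of an average-depth sample directly interpretable as log counts. Everything
downstream is a Spearman correlation *across samples within a row*, which is
invariant to monotone per-sample shifts, so the exact variant is deliberately
low-stakes; it is named in the output (`variant`), and a pure `"rank"` variant
exists for sensitivity checks. Environmental parameters join via
`append_env()` untransformed: they can be negative (winter temperatures) or
bounded (saturation percentages), and rank correlation does not care.

## The null model and the consensus network

Fixed rho cutoffs (0.6, 0.7, ...) are arbitrary; the package determines
dataset-specific thresholds. `determine_thresholds()` builds a null in which
every row of the normalized table is independently permuted across samples —
destroying all between-row association while keeping each row's marginal
distribution and tie structure — and jittered with uniform noise of amplitude
$10^{-6} \times$ the row IQR, which breaks rank ties without moving signal.
Pairwise Spearman rho over all pairs forms the null distribution; with
tolerance `alpha` (default 0.01: at most ~1% of tested pairs expected as
false edges), the co-occurrence threshold is the mean over permutations of the
per-permutation $1 - \alpha/2$ quantile, and the co-exclusion threshold the
mean $\alpha/2$ quantile. The tolerance is split between the tails because an
edge may enter on either side; the per-permutation extreme-rho summaries are
retained in the result for audit. Two randomizations are deliberately kept
distinct:

* **row shuffling + jitter** builds the null that sets thresholds (shuffling
  is what destroys association);
* **jitter only**, applied to the *observed* table in `build_consensus()`,
  probes edge stability: an edge is retained only if it passes the threshold
  in more than half (default) of the jittered replicates, and its weight is
  the mean rho over passing replicates.

Persistence so defined measures robustness to rank-tie resolution, not to
signal-scale noise — ties are endemic in sparse count rows, and an edge that
exists only under one lucky tie-break should not survive. Isolated nodes are
dropped. Co-exclusion edges (rho at or below the negative threshold) are fully
representable and flagged by `sign`; in practice positive associations
dominate strongly in seasonal plankton data.

With ~36 samples the thresholds land around 0.39 at `alpha = 0.01`; tightening
`alpha` moves them toward the 0.6 regime reported for published seasonal lake
networks, whose effective false-edge tolerance (inherited from their null-model
software) appears stricter. `alpha` is exposed and recorded in every output
for exactly this reason.

## Topology, keystones, robustness

`compute_topology()` reports the closed-form descriptors (average degree
$2E/N$, density $2E/\binom{N}{2}$), global transitivity (3 × triangles /
connected triples), and path metrics computed on the unweighted graph.
Average path length averages over **connected pairs only** and the diameter is
the maximum finite distance: consensus networks routinely have dozens of
components, and imputing infinite distances would poison both metrics.
Modularity needs a partition; seeded Louvain is used and the seed is an
argument, but note that different community algorithms give different
modularity values, so cross-study comparisons of modularity are indicative
only.

`find_key_nodes()` operationalizes "significantly higher betweenness than the
rest of the network": resample the betweenness vector with replacement
(default 10000 draws, via the `boot` package), form the bootstrap distribution
of the **mean** betweenness, and call a node significant when its score
exceeds the upper bound of the central 95% percentile interval. A key node
must also be an articulation point, so keystones are nodes that both carry
exceptional shortest-path load and hold components together. The
mean-level interval (rather than per-node intervals) is the simplest
construction consistent with bootstrapping-for-normality language common in
this literature; on a graph with uniform betweenness the interval collapses
and no node is called, which is the documented degenerate behavior.

`cascading_attack()` removes the current highest-betweenness node (ties:
lexicographically smallest id), recomputes betweenness, and repeats, recording
two loss metrics per step:

* `loss_fraction` — fraction of the initial **edges** gone (the primary
  metric, matching loss-of-connections reporting);
* `pair_loss_fraction` — fraction of initially **connected node pairs** no
  longer connected.

The two can rank attacks differently: on a bridge topology (two dense guilds
joined by one node) the highest-betweenness node is the bridge, which carries
only two edges but disconnects half of all pairs. Targeted attacks are
therefore guaranteed to dominate random removal only in the pair metric, and
that is the metric the validation suite uses for the targeted-vs-random
property; both columns are always written. `attack_summary()` reads off the
number of removals needed to reach given loss levels (defaults 50% and 95%).

## The synthetic generator as a test surface

`generate_counts()` emulates the structure of a biweekly lake time series so
that every downstream stage has ground truth:

* **Guilds.** `n_guilds` groups of `guild_size` taxa receive rank-correlated
  trajectories through a Gaussian copula. The requested `within_guild_rho` is
  a *Spearman* correlation; it is converted to the latent Pearson scale
  ($2\sin(\pi\rho_s/6)$) so the planted rank correlation is exact in
  expectation and survives any monotone normalization downstream.
* **Guild signals.** Each guild follows a smooth seasonal-style curve (cosine
  plus temporally smoothed noise). The curves are orthogonalized (QR, against
  the intercept and each other), making cross-guild latent correlation exactly
  zero — the planted truth "edges are exactly the within-guild pairs" must be
  self-consistent, and a shared seasonal driver would otherwise correlate
  guilds with each other.
* **Abundances.** Baseline log abundances are normal with SD 1.2 across taxa
  (heavy-tailed sizes); the latent abundance is a monotone transform of the
  copula variable.
* **Noise taxa.** A fraction (default 0.3) of taxa are sparse — present in a
  sample with probability 0.15 — to exercise the prevalence filter.
* **Depth.** Per-sample depths are log-normal with mean 50,000 reads and CV
  0.3 (CV 0 for exact depth); counts are a multinomial resample of relative
  abundances at that depth, so column sums equal the drawn depths exactly.
* **Environment.** Linked parameters are monotone transforms of their guild's
  latent signal plus measurement noise; unlinked ones are independent.

What the generator does *not* emulate: compositional closure effects beyond
multinomial sampling, PCR/primer bias, chimeras, zero-inflation beyond
sparsity, autocorrelated sampling gaps, or taxonomies. Passing tests therefore
demonstrate correctness of the inference machinery under controlled
correlation structure, not field performance on real metabarcoding data.

Validation problem sizes were chosen to probe each claim at desk scale: null
calibration on 500 independent taxa × 36 samples across 20 seeded runs with
200 permutations each; guild recovery on 4 guilds × 10 taxa (plus 60
background/noise taxa) at rho 0.9; metric correctness against brute-force
enumeration oracles on 200 random graphs of up to 12 nodes; determinism by
byte-comparing manifests of repeated runs.

## Pipeline and reproducibility

`run_pipeline()` orchestrates all stages per sample group (e.g. cold/warm
season), writing TSV tables, GraphML + edge-list graphs, JSON reports, CSV
attack curves, and a `manifest.json` carrying the package version, the master
seed, every derived stage seed and an FNV-1a hash of the canonical config.
Stage seeds are derived deterministically from the master seed and the stage
name, so one integer reproduces a whole run while `stage_seeds` overrides let
a single stage be re-randomized in isolation. The manifest deliberately
contains no timestamps: identical config + seed must yield byte-identical
manifests.

## Known limitations

* Correlation networks cannot distinguish direct interaction from shared
  environmental forcing; environmental nodes mitigate but do not resolve this.
* The persistence filter does not protect against false edges whose rho sits
  clearly above threshold by sampling accident; `alpha` is the only control.
* Louvain modularity values depend on the algorithm and resolution; treat
  them comparatively, within one analysis.
* Betweenness-based attack curves are hypothetical what-if scenarios; they do
  not model actual extinction likelihoods.
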