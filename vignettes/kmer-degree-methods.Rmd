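---
title: "Methods: k-mer composition and node degree in promoter-enhancer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer composition and node degree in promoter-enhancer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of what it computes, which
choices were open, and how they were settled.

## The setting

A promoter-capture Hi-C experiment yields a table of promoter–enhancer
interactions. We treat it as a bipartite graph: promoters and enhancers
are nodes, interactions are edges, and the degree of a node is the
number of distinct partners it contacts. The question the package
addresses is whether a node's position in this graph — its type and its
degree — is reflected in the DNA sequence of the underlying region, as
summarized by its k-mer content.

## Region standardization

Regions of heterogeneous length are not comparable in raw k-mer counts,
so every node is replaced by a fixed window (default 1000 bp, must be
even) centered at its anchor: the TSS for a promoter, the midpoint
`floor((start+end)/2)` of the fragment for an enhancer. Internally all
coordinates are 0-based half-open; the TSV/XLSX readers convert from
1-based inputs, BED-style input is taken as already 0-based.

Three conventions matter here:

* **Plus strand only.** Sequence is always read from the + strand;
  promoter strand is used only to locate the TSS, never to
  reverse-complement. Counting one strand for both node types keeps
  promoter and enhancer vectors directly comparable, and means AAAA and
  TTTT are distinct coordinates.
* **Drop, never clip.** A window that runs off its chromosome (or whose
  chromosome is missing from the FASTA) is dropped with a warning and
  counted, so every retained vector comes from exactly `window` bases.
  Clipping would silently shrink counts and bias distances downward.
* **Duplicates collapse.** Exact duplicate promoter–enhancer pairs are
  collapsed on read (unique interactions); `keep_duplicates = TRUE`
  preserves multiplicity for sensitivity checks.

## K-mer counting

Counts are over all overlapping windows (length L gives L−k+1 windows);
any window containing a non-ACGT character contributes to no k-mer —
skipped entirely, not partially matched. Vectors are indexed by the
lexicographic order A<C<G<T so they are portable. Counting is delegated
to `Biostrings::oligonucleotideFrequency`, which implements exactly
these conventions; the test suite holds it against a naive
sliding-window oracle on randomized sequences. k is capped at 8 (65,536
coordinates); the analyses use k = 4, where the 256-dimensional space is
large enough to be informative at 1 kb and small enough that per-degree
averages are stable. CpG-containing k-mers (substring "CG", 5′→3′) are
enumerated exactly; there are 47 of 256 at k = 4.

## Degree profiles and their clustering

For each k-mer and node type, the profile of its mean count at degrees
1..D (default D = 10; nodes of higher degree stay in the network but
outside the profiles) is computed; the promoter and enhancer profiles of
the same k-mer are joined head to tail (promoter first) and centered by
subtracting the joint mean, so clustering sees the *shape* of the degree
dependence rather than base abundance. Degrees with no node of one type
are excluded from the joint profile (the run reports the restriction).

Clustering is classical PAM (build + swap, `cluster::pam`, Euclidean)
plus seeded random restarts, keeping the lowest total cost; medoids are
always members of the data. The number of clusters is selected by the
gap statistic with reference sets drawn uniformly over the
per-coordinate range of the data (the simpler of Tibshirani's two
reference schemes, no PCA rotation; B = 50 reference draws by default)
and the usual one-standard-error rule: the smallest k whose gap is
within one SE of the next. The gap machinery is `cluster::clusGap` +
`maxSE`; the planted-structure recovery and determinism are tested.

Each cluster is annotated with its member k-mers, CpG-containing /
GC-only / AT-only member counts, and median half-profiles. Monotonicity
labels use the Spearman correlation of a median profile against degree
with threshold |rho| ≥ 0.5 — an intentionally coarse, qualitative
cutoff for describing clusters as increasing / decreasing / flat.

One labeling subtlety was settled empirically. A cluster-level trend
computed as the Spearman of the *concatenated* median halves against the
repeated degree vector is structurally capped near 0.49 when the two
halves sit at different levels (the centered promoter half of a GC-rich
k-mer is systematically above its enhancer half, so the between-half
rank offset dominates), and per-half labels are noisy where a degree
cell holds only a handful of nodes. The cluster `trend_label` is
therefore the mean of the two within-half Spearman correlations,
computed over degrees with at least `min_cell_n = 5` nodes of both types
(all degrees if fewer than three qualify). The CpG-enrichment contrast
(one-sided Fisher exact test of CpG membership, increasing vs decreasing
clusters) uses this label; the per-half labels remain in the summary for
description.

## The lakd statistic and its trends

The k-mer distance of an interacting pair is the Euclidean distance
between their count vectors; a node's lakd is the arithmetic mean over
its incident edges. The measure is deliberately asymmetric in its
grouping: the same edge set averaged by promoter or by enhancer gives
different distributions, and their comparison (two-sample KS, asymptotic
p at effective size $n_x n_y/(n_x+n_y)$ — appropriate for the sample
sizes involved, exact small-sample p is out of scope) is the package's
local similarity result. A useful exact identity for validation: the
degree-weighted mean of lakd over promoters, the degree-weighted mean
over enhancers, and the plain mean of all edge distances coincide.

Degree trends are fit at node level — OLS of lakd on degree over
individual nodes plus Spearman with average ranks — not on per-degree
means. Both are computable, but node-level regression is the default
because the per-degree means hide the within-degree sample sizes that
the p-values must reflect. Per-degree means are reported alongside for
plotting. The same applies to the composition trends (%GC and GG, CC,
GC, CG counts vs degree), where the trend table's correlation column is
Spearman by default with a Pearson flag, and fold changes are anchored
at degree 1 (FC(1) = 1 exactly; absence of degree-1 nodes is an error,
not a silent renormalization). Edge-level structure is tabulated on the
(promoter degree × enhancer degree) grid, by default over degrees 1–5,
with per-cell frequency (relative to *all* edges, so a full-range grid
sums to 1) and mean edge distance.

## The synthetic generator

The generator exists so that every stage runs and is testable with no
downloads. It emulates, at desk scale, the statistical structure the
analysis assumes:

* **Network shape.** Promoters draw degrees from a zero-truncated
  negative binomial (NB mean parameter 6, dispersion 2; truncated mean
  ≈ 6.4); enhancers are degree 1 with probability 0.8 and otherwise
  2 + geometric(0.6) (mean ≈ 1.33). Defaults of 345 promoters and 1,655
  enhancers (2,000 nodes) make the two sides' expected stub totals agree
  while keeping the promoter:enhancer ratio (≈ 1:4.8) close to real
  capture data (≈ 1:4.5). Wiring is a configuration model: stubs are
  shuffled and paired; stub totals are equalized by resampling the
  smaller-total side (best of up to 1,000 redraws, any small residual
  fixed by ±1 on distinct random nodes); duplicate edges are re-paired,
  with a capped retry and drop-with-message fallback, so the graph is
  simple like the deduplicated real tables.
* **Sequences.** Each node gets one synthetic "chromosome" of exactly
  one window, generated by a first-order Markov chain over A,C,G,T with
  stationary GC propensity `g = clamp(gc_base_type + 0.01·(degree−1),
  0.05, 0.95)` (bases 0.55 for promoters, 0.45 for enhancers) and the
  C→G transition multiplied by a CpG-depletion factor (0.8 promoters,
  0.3 enhancers) with the C row renormalized. First order is enough to
  control GC% and CpG density independently, which is all the statistics
  under test require.
* **Seeding.** One master seed feeds named substreams (network,
  sequences) so stages are independently reproducible; per-sequence
  seeds mix the node index in with a multiplicative hash (a linear
  seed spacing produced measurable cross-stream correlations in
  dinucleotide counts).

These defaults are the package's study conditions: promoter GC above
enhancer GC, a shared positive GC-degree slope, and stronger CpG
depletion in enhancers jointly produce the directional results the
pipeline is designed to detect — the promoter-grouped lakd distribution
shifted toward smaller distances, a negative enhancer-grouped and
positive promoter-grouped lakd-degree slope, positive composition-degree
correlations, and CpG enrichment of profile clusters that increase with
degree.

What the generator does **not** emulate: real base composition beyond
first order (no repeats, no CpG islands as discrete elements, no
isochores), mappability or assembly artifacts, contact-frequency noise,
or any correlation between interaction distance and sequence. Passing
tests therefore demonstrate that the pipeline recovers planted
degree–composition structure of realistic magnitude from data of
realistic shape — not that real genomes behave this way.

## Problem sizes and runtime choices

The shipped analyses and tests run at 2,000 nodes, 1 kb windows,
k = 4, D = 10, B = 50 gap references, and 20-seed replications for the
type-I-control and gap-recovery properties; the full test suite and the
acceptance script each complete in about a minute on one CPU. All
statistical checks on stochastic outputs use fixed seeds.

## Known limitations

* The number of clusters found by PAM + gap on any given dataset is
  sensitive to the clustering conventions; only the qualitative cluster
  structure (monotone trends, CpG separation) is asserted, not a
  particular k or membership.
* The XLSX/BED adapters require a user-supplied column mapping; the
  published supplementary tables do not print a schema, so none is
  guessed.
* Only unweighted node degree is analyzed; contact frequency (how often
  a given pair interacts) is a related but distinct quantity and out of
  scope.
* KS p-values are asymptotic; trend p-values assume independent nodes,
  ignoring that interacting regions share edges.
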