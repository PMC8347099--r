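# kmernet

Sequence composition and node degree in promoter–enhancer interaction
networks.

Capture Hi-C maps of promoter–enhancer contacts can be read as a
bipartite graph: promoters and enhancers are nodes, interactions are
edges, and a node's *degree* is the number of partner regions it
contacts. `kmernet` asks whether the graph position of a regulatory
region is reflected in its DNA sequence: it standardizes every region to
a fixed 1 kb window, summarizes each window by its vector of overlapping
k-mer counts (k = 4 gives 256 coordinates, counted on the + strand
only), and relates composition to node type and node degree.

The package is aimed at regulatory-genomics analysts working with
promoter-capture Hi-C style interaction tables (e.g. mouse ES or human
keratinocyte datasets) plus a genome FASTA, and at anyone who wants the
analysis reproducible end to end without downloads: a synthetic-data
module generates bipartite networks and degree-dependent sequences with
the statistical structure the method assumes.

## The statistics

For two interacting regions with k-mer count vectors $x, y \in
\mathbb{N}^{4^k}$, their **k-mer distance** is the Euclidean norm
$d(x,y) = \lVert x - y\rVert_2$. The **local average k-mer distance
(lakd)** of a node $v$ with incident edges $E_v$ is

$$\mathrm{lakd}(v) = \frac{1}{|E_v|} \sum_{(v,u) \in E_v} d(x_v, x_u),$$

i.e. a promoter's mean distance to the enhancers it contacts, and
conversely for enhancers. Grouping lakd by node type and stratifying by
degree gives the package's headline comparisons: a Kolmogorov–Smirnov
test between the promoter-grouped and enhancer-grouped distributions,
and node-level OLS slopes / Spearman correlations of lakd on degree.

Per-k-mer **degree profiles** (mean count at degrees 1..10, separately
per node type) are joined head to tail (promoter half then enhancer
half, length 20), centered, and clustered with PAM k-medoids at the k
chosen by the gap statistic; clusters are annotated with their CpG
content (47 of the 256 4-mers contain CpG) and the monotonicity of their
median profiles, and CpG enrichment of increasing vs decreasing clusters
is tested with a one-sided Fisher exact test. Composition trends (%GC
and the GG, CC, GC, CG dinucleotide counts vs degree, with fold changes
relative to degree 1) complete the picture.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (no downloads):

```sh
Rscript analysis/01_simulate.R           # network + sequences + truth table
Rscript analysis/02_kmer_composition.R   # 4-mer counts and rankings
Rscript analysis/03_profiles_clustering.R
Rscript analysis/04_lakd_distance.R
Rscript analysis/05_composition_trends.R
```

On the default conditions (2,000 nodes, seed 20210728) stage 4 prints:

```
mean lakd: promoters 62.67, enhancers 71.83 (promoter shifted left)
KS: D = 0.328, p = 0
promoter-grouped lakd vs degree: slope 2.261 (p 6.71e-141), rho 0.879 (p 1.58e-112)
enhancer-grouped lakd vs degree: slope -1.290 (p 0.0292), rho -0.031 (p 0.207)
```

Promoters are on average *closer* in k-mer space to their interacting
enhancers than vice versa (the KS shift), and the degree trends run in
opposite directions: higher-degree enhancers become more similar to
promoters (negative slope), higher-degree promoters less similar to
enhancers (positive slope). Stage 3 reports the cluster structure of the
degree profiles and the CpG enrichment of the increasing clusters
(`OR Inf, p = 3.41e-15` on these conditions), and stage 5 prints the
composition trend table — all five G/C metrics correlate positively with
degree in both node types.

The same functions run on real data: read the interaction table with
`read_interaction_table()` (generic TSV, BED-style contact export, or an
XLSX supplementary table via a user-supplied column mapping), the genome
with `read_genome()`, and start from `run_composition_pipeline()`.

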