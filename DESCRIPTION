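Package: kmernet
Title: K-mer Composition and Node Degree in Promoter-Enhancer Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequence composition of promoter-enhancer
    interaction networks. Standardizes regulatory regions to fixed windows,
    counts k-mers on the plus strand, builds per-k-mer average-count profiles
    as a function of node degree, clusters joint promoter/enhancer profiles
    with k-medoids selected by the gap statistic, and computes the local
    average k-mer distance (lakd) of each node together with its
    degree-stratified trends, GC/dinucleotide composition trends and
    edge-degree grids. Includes a synthetic bipartite network and sequence
    generator with degree-dependent GC and CpG content so the whole pipeline
    is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    methods,
    stats,
    utils
Suggests:
    readxl,
    jsonlite,
    testthat (>= 3.0.0),
    zip
Config/testthat/edition: 3
RoxygenNote: 7.3.3
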