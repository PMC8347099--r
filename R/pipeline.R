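#' Run the composition pipeline from an interaction table and genome
#'
#' Convenience driver chaining the stages: read (or take) the interaction
#' table and genome, standardize all regions to the window, extract
#' sequences, build and prune the network, count k-mers, and compute
#' composition statistics. Downstream statistics (profiles, clustering,
#' lakd, trends, grids) take the returned pieces.
#'
#' @param interactions An \code{interaction_table}, or a file path (read
#'   with \code{dialect}/\code{mapping}).
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param k k-mer length (default 4).
#' @param window Standardized window in bp (default 1000).
#' @param dialect,mapping,keep_duplicates Passed to
#'   \code{\link{read_interaction_table}} when \code{interactions} is a
#'   path.
#' @return A list: \code{network} (pruned to nodes with sequences),
#'   \code{nodes} (retained standardized node table, degrees recomputed
#'   after pruning), \code{sequences}, \code{kmat} (k-mer count matrix),
#'   \code{composition} (per-node composition stats), \code{dropped},
#'   \code{k}, \code{window}.
#' @export
run_composition_pipeline <- function(interactions, genome, k = 4L,
                                     window = 1000L,
                                     dialect = "generic_tsv",
                                     mapping = NULL,
                                     keep_duplicates = FALSE) {
  if (is.character(interactions))
    interactions <- read_interaction_table(interactions, dialect = dialect,
                                           mapping = mapping,
                                           keep_duplicates = keep_duplicates)
  if (is.character(genome))
    genome <- read_genome(genome)
  nodes <- standardize_regions(nodes_from_interactions(interactions),
                               window = window)
  ex <- extract_sequences(genome, nodes)
  net <- build_network(interactions)
  if (nrow(ex$dropped))
    net <- prune_network(net, ex$nodes$node_id)
  # recompute degrees on the pruned network so annotation matches
  deg <- c(net$promoter_degree, net$enhancer_degree)
  kept <- ex$nodes[ex$nodes$node_id %in% names(deg), , drop = FALSE]
  kept$degree <- as.integer(deg[kept$node_id])
  seqs <- ex$sequences[kept$node_id]
  kmat <- count_kmers(seqs, k = k)
  comp <- composition_stats(seqs, nodes = kept)
  list(network = net, nodes = kept, sequences = seqs, kmat = kmat,
       composition = comp, dropped = ex$dropped, k = k, window = window)
}
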