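#' Node table from an interaction table
#'
#' Collapses an interaction table to its unique nodes: one row per promoter
#' (anchored at the TSS) and one per enhancer (anchored at the midpoint
#' \code{floor((start+end)/2)} of its fragment). Node degrees are attached
#' from the edge list.
#'
#' @param interactions An \code{interaction_table} (see
#'   \code{\link{read_interaction_table}}).
#' @return A data.frame with columns \code{node_id, node_type, chrom,
#'   anchor, strand, degree}; \code{anchor} is 0-based.
#' @export
nodes_from_interactions <- function(interactions) {
  p <- interactions[!duplicated(interactions$promoter_id),
                    c("promoter_id", "p_chrom", "p_anchor", "p_strand")]
  e <- interactions[!duplicated(interactions$enhancer_id),
                    c("enhancer_id", "e_chrom", "e_start", "e_end")]
  pd <- table(interactions$promoter_id)
  ed <- table(interactions$enhancer_id)
  nodes <- rbind(
    data.frame(node_id = p$promoter_id, node_type = "promoter",
               chrom = p$p_chrom, anchor = p$p_anchor,
               strand = p$p_strand,
               degree = as.integer(pd[p$promoter_id]),
               stringsAsFactors = FALSE),
    data.frame(node_id = e$enhancer_id, node_type = "enhancer",
               chrom = e$e_chrom,
               anchor = floor((e$e_start + e$e_end) / 2),
               strand = "unknown",
               degree = as.integer(ed[e$enhancer_id]),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  nodes
}

#' Standardize regions to a fixed window
#'
#' Every node is replaced by the fixed-width window
#' \code{[anchor - window/2, anchor + window/2)} centered at its anchor
#' (TSS for promoters, fragment midpoint for enhancers). Strand is used
#' only to locate the TSS upstream of this call, never to flip the window.
#' Standardization is idempotent: re-standardizing returns the same
#' intervals because the anchor is retained.
#'
#' @param nodes Node table from \code{\link{nodes_from_interactions}} (or
#'   any data.frame with \code{anchor}).
#' @param window Even window width in bp (default 1000).
#' @return The node table with \code{start}/\code{end} columns added
#'   (0-based half-open, width exactly \code{window}).
#' @export
standardize_regions <- function(nodes, window = 1000L) {
  window <- as.integer(window)
  if (window <= 0L || window %% 2L != 0L)
    stop("window must be a positive even integer")
  if (is.null(nodes$anchor) || anyNA(nodes$anchor))
    stop("every region needs an anchor position")
  nodes$start <- nodes$anchor - window %/% 2L
  nodes$end <- nodes$anchor + window %/% 2L
  attr(nodes, "window") <- window
  nodes
}

#' Extract standardized sequences from a genome
#'
#' Pulls the + strand sequence of every standardized window. Windows that
#' run past a chromosome end (or start before position 0), or whose
#' chromosome is absent from the genome, are dropped with a warning and
#' counted — never clipped, so all retained sequences have identical
#' length and their k-mer vectors are directly comparable.
#'
#' @param genome A \code{DNAStringSet} from \code{\link{read_genome}}.
#' @param nodes Standardized node table from
#'   \code{\link{standardize_regions}}.
#' @return A list with \code{sequences} (a \code{DNAStringSet} named by
#'   \code{node_id}), \code{nodes} (the retained node rows), and
#'   \code{dropped} (data.frame of dropped node ids and reasons).
#' @export
extract_sequences <- function(genome, nodes) {
  if (is.null(nodes$start))
    stop("nodes must be standardized first (see standardize_regions)")
  chr_len <- stats::setNames(Biostrings::width(genome), names(genome))
  known <- nodes$chrom %in% names(chr_len)
  inb <- known & nodes$start >= 0 &
    nodes$end <= ifelse(known, chr_len[nodes$chrom], 0L)
  dropped <- data.frame(
    node_id = nodes$node_id[!inb],
    reason = ifelse(known[!inb], "out_of_bounds", "unknown_chromosome"),
    stringsAsFactors = FALSE)
  if (nrow(dropped))
    warning(nrow(dropped), " region(s) dropped (",
            sum(dropped$reason == "out_of_bounds"), " out of bounds, ",
            sum(dropped$reason == "unknown_chromosome"),
            " on chromosomes absent from the genome)")
  kept <- nodes[inb, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(
    Biostrings::subseq(genome[kept$chrom],
                       start = kept$start + 1L, end = kept$end))
  names(seqs) <- kept$node_id
  list(sequences = seqs, nodes = kept, dropped = dropped)
}
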