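#' All k-mers in lexicographic order
#'
#' @param k k-mer length.
#' @return Character vector of the 4^k k-mers over A<C<G<T, lexicographic.
#' @export
kmer_names <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

#' Count k-mers in sequences
#'
#' Overlapping windows on the + strand only; no reverse-complement
#' canonicalization (AAAA and TTTT are distinct coordinates). Any window
#' containing a non-ACGT character contributes to no k-mer, so the counts
#' of a length-L sequence sum to L - k + 1 exactly when it is pure ACGT.
#'
#' @param sequences A character vector, \code{DNAString}, or
#'   \code{DNAStringSet}.
#' @param k k-mer length (1..8).
#' @return An integer matrix, one row per sequence (named when the input
#'   is named), one column per k-mer in lexicographic order.
#' @export
count_kmers <- function(sequences, k = 4L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 8L) stop("k > 8 is not supported")
  if (is.character(sequences) || methods::is(sequences, "DNAString"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (any(Biostrings::width(sequences) < k))
    stop("all sequences must be at least k bases long")
  m <- Biostrings::oligonucleotideFrequency(sequences, width = k, step = 1L)
  rownames(m) <- names(sequences)
  m
}

#' K-mers containing a CpG dinucleotide
#'
#' Enumerates all k-mers with "CG" (C immediately followed by G, 5'->3') as
#' a substring. There are 47 such 4-mers.
#'
#' @param k k-mer length.
#' @return Character vector of CpG-containing k-mers (empty for k < 2).
#' @export
cpg_kmer_set <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k < 2L) return(character(0))
  km <- kmer_names(k)
  km[grepl("CG", km, fixed = TRUE)]
}

#' Per-sequence GC and G/C-dinucleotide composition
#'
#' GC percentage is 100 * (#G + #C) / (#A + #C + #G + #T) -- ambiguous
#' bases are excluded from the denominator. GG, CC, GC and CG are counted
#' as overlapping dinucleotides on the + strand; CG is the 5'->3' CpG.
#' Sequences with no unambiguous base are dropped with a warning.
#'
#' @param sequences As for \code{\link{count_kmers}}.
#' @param nodes Optional node table (node_id, node_type, degree) to merge
#'   in by sequence name.
#' @return A data.frame with \code{node_id, gc_percent, GG, CC, GC, CG}
#'   (plus \code{node_type}/\code{degree} when \code{nodes} is given).
#' @export
composition_stats <- function(sequences, nodes = NULL) {
  c1 <- count_kmers(sequences, k = 1L)
  c2 <- count_kmers(sequences, k = 2L)
  tot <- rowSums(c1)
  allN <- tot == 0L
  if (any(allN)) {
    warning(sum(allN), " all-ambiguous sequence(s) dropped from composition")
    c1 <- c1[!allN, , drop = FALSE]
    c2 <- c2[!allN, , drop = FALSE]
    tot <- tot[!allN]
  }
  out <- data.frame(
    node_id = if (is.null(rownames(c1))) as.character(seq_len(nrow(c1)))
              else rownames(c1),
    gc_percent = as.numeric(100 * (c1[, "G"] + c1[, "C"]) / tot),
    GG = as.integer(c2[, "GG"]), CC = as.integer(c2[, "CC"]),
    GC = as.integer(c2[, "GC"]), CG = as.integer(c2[, "CG"]),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(nodes)) {
    idx <- match(out$node_id, nodes$node_id)
    out$node_type <- nodes$node_type[idx]
    out$degree <- nodes$degree[idx]
  }
  out
}

#' Mean k-mer count vector for one node type
#'
#' @param kmat K-mer count matrix (rows = nodes) from
#'   \code{\link{count_kmers}}.
#' @param node_type Character vector of node types parallel to the rows.
#' @param type The type to average over.
#' @return Named numeric vector: unweighted per-k-mer arithmetic mean.
#' @export
mean_count_by_type <- function(kmat, node_type, type) {
  sel <- node_type == type
  if (!any(sel)) stop("no nodes of type '", type, "'")
  colMeans(kmat[sel, , drop = FALSE])
}

#' Rank k-mers by average count in one node type
#'
#' Ranks all k-mers by descending mean count in the chosen node type (ties
#' broken lexicographically) and reports the maximal head-run: the longest
#' prefix of the ranking in which the chosen type's mean also exceeds the
#' other type's mean. On the mouse ES data this construct gives the top-23
#' promoter k-mers and the top-6 enhancer k-mers.
#'
#' @param mean_promoter,mean_enhancer Named mean count vectors of equal
#'   length (see \code{\link{mean_count_by_type}}).
#' @param by Which type to rank on.
#' @return A list with \code{ranking} (data.frame \code{kmer,
#'   mean_promoter, mean_enhancer} in rank order) and \code{head_run}
#'   (integer length of the head-run).
#' @export
rank_kmers <- function(mean_promoter, mean_enhancer,
                       by = c("promoter", "enhancer")) {
  by <- match.arg(by)
  if (length(mean_promoter) != length(mean_enhancer))
    stop("mean vectors must have equal length")
  km <- names(mean_promoter)
  chosen <- if (by == "promoter") mean_promoter else mean_enhancer
  other <- if (by == "promoter") mean_enhancer else mean_promoter
  ord <- order(-chosen, km)
  ranking <- data.frame(kmer = km[ord],
                        mean_promoter = unname(mean_promoter[ord]),
                        mean_enhancer = unname(mean_enhancer[ord]),
                        stringsAsFactors = FALSE)
  above <- chosen[ord] > other[ord]
  head_run <- if (!length(above) || !above[1]) 0L
              else which.min(c(above, FALSE)) - 1L
  list(ranking = ranking, head_run = as.integer(head_run))
}
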