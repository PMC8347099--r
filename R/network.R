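#' Build the bipartite promoter-enhancer network
#'
#' @param interactions An \code{interaction_table} (deduplicated) or any
#'   data.frame with \code{promoter_id} and \code{enhancer_id} columns.
#' @return A list of class \code{pe_network}: \code{edges} (data.frame
#'   \code{promoter_id, enhancer_id}), \code{promoter_degree} and
#'   \code{enhancer_degree} (named integer vectors).
#' @export
build_network <- function(interactions) {
  edges <- data.frame(promoter_id = as.character(interactions$promoter_id),
                      enhancer_id = as.character(interactions$enhancer_id),
                      stringsAsFactors = FALSE)
  both <- intersect(unique(edges$promoter_id), unique(edges$enhancer_id))
  if (length(both))
    stop("node id(s) appear as both promoter and enhancer ",
         "(bipartite assumption violated): ", both[1])
  pd <- table(edges$promoter_id)
  ed <- table(edges$enhancer_id)
  net <- list(
    edges = edges,
    promoter_degree = stats::setNames(as.integer(pd), names(pd)),
    enhancer_degree = stats::setNames(as.integer(ed), names(ed)))
  class(net) <- "pe_network"
  net
}

#' @export
print.pe_network <- function(x, ...) {
  cat("bipartite promoter-enhancer network\n")
  cat("  promoters:", length(x$promoter_degree),
      " enhancers:", length(x$enhancer_degree),
      " edges:", nrow(x$edges), "\n")
  cat("  promoter degree: ",
      paste(range(x$promoter_degree), collapse = ".."),
      " (mean ", round(mean(x$promoter_degree), 2), ")\n", sep = "")
  cat("  enhancer degree: ",
      paste(range(x$enhancer_degree), collapse = ".."),
      " (mean ", round(mean(x$enhancer_degree), 2), ")\n", sep = "")
  invisible(x)
}

#' Restrict a network to nodes with available sequence vectors
#'
#' Drops every edge with a missing endpoint and recomputes degrees; used
#' before \code{\link{lakd}} when some regions were dropped at sequence
#' extraction.
#'
#' @param network A \code{pe_network}.
#' @param keep_ids Character vector of node ids to retain.
#' @return A pruned \code{pe_network}.
#' @export
prune_network <- function(network, keep_ids) {
  keep <- network$edges$promoter_id %in% keep_ids &
    network$edges$enhancer_id %in% keep_ids
  if (!all(keep))
    message(sum(!keep), " edge(s) removed with dropped endpoints")
  build_network(network$edges[keep, , drop = FALSE])
}

#' Edge-degree grid of interaction frequency and mean k-mer distance
#'
#' Groups edges simultaneously by promoter degree and enhancer degree.
#' Each cell carries the edge count, the frequency (cell count divided by
#' the total edge count of the whole network, so full-range frequencies
#' sum to 1), and -- when \code{edge_distances} is given -- the arithmetic
#' mean k-mer distance of the cell's edges (NA for empty cells).
#'
#' @param network A \code{pe_network}.
#' @param edge_distances Optional numeric vector of per-edge distances,
#'   parallel to \code{network$edges} rows (see
#'   \code{\link{edge_kmer_distances}}).
#' @param degree_range Integer two-vector \code{c(lo, hi)} of degrees to
#'   tabulate on both axes (default \code{c(1, 5)}).
#' @return A list of class \code{edge_degree_grid} with matrices
#'   \code{count}, \code{freq} and (optionally) \code{mean_distance},
#'   rows = promoter degree, columns = enhancer degree.
#' @export
edge_degree_grid <- function(network, edge_distances = NULL,
                             degree_range = c(1L, 5L)) {
  lo <- as.integer(degree_range[1]); hi <- as.integer(degree_range[2])
  if (lo > hi) stop("degree_range must be increasing")
  if (!is.null(edge_distances) &&
      length(edge_distances) != nrow(network$edges))
    stop("edge_distances must be parallel to the edge list")
  pd <- network$promoter_degree[network$edges$promoter_id]
  ed <- network$enhancer_degree[network$edges$enhancer_id]
  degs <- lo:hi
  n <- length(degs)
  lab <- as.character(degs)
  count <- matrix(0L, n, n, dimnames = list(promoter_degree = lab,
                                            enhancer_degree = lab))
  inr <- pd >= lo & pd <= hi & ed >= lo & ed <= hi
  tab <- table(factor(pd[inr], levels = degs),
               factor(ed[inr], levels = degs))
  count[] <- as.integer(tab)
  out <- list(count = count,
              freq = count / nrow(network$edges),
              degree_range = c(lo, hi))
  if (!is.null(edge_distances)) {
    md <- matrix(NA_real_, n, n, dimnames = dimnames(count))
    s <- tapply(edge_distances[inr],
                list(factor(pd[inr], levels = degs),
                     factor(ed[inr], levels = degs)),
                mean)
    md[] <- as.numeric(s)
    out$mean_distance <- md
  }
  class(out) <- "edge_degree_grid"
  out
}
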