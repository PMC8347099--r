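#' Configuration for the synthetic promoter-enhancer generator
#'
#' Defaults emulate the shape of published capture Hi-C promoter-enhancer
#' networks at desk scale (2,000 nodes): a promoter:enhancer ratio near
#' 1:4.8 (chosen so the two sides' expected stub totals agree, close to
#' the 1:4.5 seen in real capture data), promoters with a broad degree
#' distribution (zero-truncated negative binomial with NB mean parameter
#' 6, truncated mean about 6.4), enhancers mostly degree 1 with a
#' geometric tail (mean about 1.33), 1 kb windows, promoters more GC-rich
#' than enhancers, GC propensity rising with node degree, and CpG
#' depletion stronger in enhancers than promoters.
#'
#' @param n_promoters,n_enhancers Node counts.
#' @param promoter_degree_mean,promoter_degree_dispersion Zero-truncated
#'   negative binomial law for promoter degrees (mean, size).
#' @param enhancer_p1 Probability that an enhancer has degree exactly 1.
#' @param enhancer_geom_p Success probability of the geometric tail: with
#'   probability \code{1 - enhancer_p1} the degree is
#'   \code{1 + rgeom(enhancer_geom_p) + 1}.
#' @param window Sequence window in bp.
#' @param gc_base_promoter,gc_base_enhancer Degree-1 GC propensity.
#' @param gc_degree_slope GC propensity increase per unit degree.
#' @param cpg_depletion_promoter,cpg_depletion_enhancer Multiplicative
#'   factors in (0, 1] applied to the C->G transition probability.
#' @param seed Master seed; named substreams (network, sequences) are
#'   derived from it so stages are independently reproducible.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_promoters = 345L,
                             n_enhancers = 1655L,
                             promoter_degree_mean = 6,
                             promoter_degree_dispersion = 2,
                             enhancer_p1 = 0.8,
                             enhancer_geom_p = 0.6,
                             window = 1000L,
                             gc_base_promoter = 0.55,
                             gc_base_enhancer = 0.45,
                             gc_degree_slope = 0.01,
                             cpg_depletion_promoter = 0.8,
                             cpg_depletion_enhancer = 0.3,
                             seed = 20210728L) {
  cfg <- list(n_promoters = as.integer(n_promoters),
              n_enhancers = as.integer(n_enhancers),
              promoter_degree_mean = promoter_degree_mean,
              promoter_degree_dispersion = promoter_degree_dispersion,
              enhancer_p1 = enhancer_p1,
              enhancer_geom_p = enhancer_geom_p,
              window = as.integer(window),
              gc_base_promoter = gc_base_promoter,
              gc_base_enhancer = gc_base_enhancer,
              gc_degree_slope = gc_degree_slope,
              cpg_depletion_promoter = cpg_depletion_promoter,
              cpg_depletion_enhancer = cpg_depletion_enhancer,
              seed = as.integer(seed))
  stopifnot(cfg$n_promoters >= 1L, cfg$n_enhancers >= 1L,
            cfg$gc_base_promoter > 0, cfg$gc_base_promoter < 1,
            cfg$gc_base_enhancer > 0, cfg$gc_base_enhancer < 1,
            cfg$cpg_depletion_promoter > 0, cfg$cpg_depletion_promoter <= 1,
            cfg$cpg_depletion_enhancer > 0, cfg$cpg_depletion_enhancer <= 1,
            cfg$enhancer_p1 >= 0, cfg$enhancer_p1 <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# named substreams off the master seed, kept well below 2^31
.substream <- function(seed, name) {
  (as.integer(seed) %% 1000000000L) +
    switch(name, network = 101L, sequences = 202L,
           stop("unknown substream: ", name))
}

.draw_promoter_degrees <- function(n, mu, size) {
  # zero-truncated negative binomial by inverse CDF on (P(X=0), 1]
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, min = p0, max = 1)
  pmax(as.integer(stats::qnbinom(u, mu = mu, size = size)), 1L)
}

.draw_enhancer_degrees <- function(n, p1, geom_p) {
  tail <- stats::runif(n) > p1
  d <- rep(1L, n)
  d[tail] <- 2L + stats::rgeom(sum(tail), geom_p)
  d
}

#' Generate a bipartite network by the configuration model
#'
#' Draws target degrees for both sides, equalizes the stub totals by
#' resampling the smaller-total side (best of up to 1,000 redraws, any
#' small residual fixed by +/-1 on distinct random nodes, degrees kept
#' >= 1), and wires stubs uniformly at random. Duplicate edges are
#' resolved by re-pairing (capped); any remaining duplicates are dropped
#' with a message. Deterministic given the config seed.
#'
#' @param config A \code{synthetic_config}.
#' @return A list: \code{network} (a \code{pe_network}),
#'   \code{target_degrees} (data.frame \code{node_id, node_type, degree}).
#' @export
generate_network <- function(config) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.substream(config$seed, "network"))

  p_ids <- sprintf("P%05d", seq_len(config$n_promoters))
  e_ids <- sprintf("E%05d", seq_len(config$n_enhancers))
  pdeg <- .draw_promoter_degrees(config$n_promoters,
                                 config$promoter_degree_mean,
                                 config$promoter_degree_dispersion)
  edeg <- .draw_enhancer_degrees(config$n_enhancers, config$enhancer_p1,
                                 config$enhancer_geom_p)

  # equalize stub totals by resampling the smaller-total side
  if (sum(pdeg) != sum(edeg)) {
    small_is_p <- sum(pdeg) < sum(edeg)
    target <- if (small_is_p) sum(edeg) else sum(pdeg)
    redraw <- function() if (small_is_p)
      .draw_promoter_degrees(config$n_promoters,
                             config$promoter_degree_mean,
                             config$promoter_degree_dispersion)
    else .draw_enhancer_degrees(config$n_enhancers, config$enhancer_p1,
                                config$enhancer_geom_p)
    best <- if (small_is_p) pdeg else edeg
    for (i in seq_len(1000L)) {
      if (sum(best) == target) break
      cand <- redraw()
      if (abs(sum(cand) - target) < abs(sum(best) - target)) best <- cand
    }
    resid <- target - sum(best)
    if (resid != 0L) {
      eligible <- which(best >= 1L + (resid < 0L))
      if (abs(resid) > length(eligible))
        stop("degree sequences infeasible after 1000 retries")
      adj <- eligible[sample.int(length(eligible), abs(resid))]
      best[adj] <- best[adj] + sign(resid)
    }
    if (small_is_p) pdeg <- best else edeg <- best
  }

  p_stubs <- sample(rep(p_ids, pdeg))
  e_stubs <- sample(rep(e_ids, edeg))
  for (i in seq_len(200L)) {
    key <- paste(p_stubs, e_stubs, sep = "\r")
    dup <- duplicated(key)
    if (!any(dup)) break
    idx <- which(dup)
    swap <- sample(length(e_stubs), length(idx), replace = FALSE)
    tmp <- e_stubs[idx]
    e_stubs[idx] <- e_stubs[swap]
    e_stubs[swap] <- tmp
  }
  key <- paste(p_stubs, e_stubs, sep = "\r")
  if (any(duplicated(key))) {
    message(sum(duplicated(key)),
            " duplicate edge(s) dropped after re-pairing cap")
    keep <- !duplicated(key)
    p_stubs <- p_stubs[keep]; e_stubs <- e_stubs[keep]
  }
  net <- build_network(data.frame(promoter_id = p_stubs,
                                  enhancer_id = e_stubs,
                                  stringsAsFactors = FALSE))
  target <- data.frame(
    node_id = c(p_ids, e_ids),
    node_type = rep(c("promoter", "enhancer"),
                    c(config$n_promoters, config$n_enhancers)),
    degree = c(pdeg, edeg), stringsAsFactors = FALSE)
  list(network = net, target_degrees = target)
}

# Vectorized first-order Markov chains over A,C,G,T.
# g: per-sequence stationary GC propensity; depletion: per-sequence CpG
# factor multiplying the C->G transition probability (C row renormalized).
.markov_seqs <- function(n, g, depletion, window) {
  bases <- c("A", "C", "G", "T")
  pA <- (1 - g) / 2; pC <- g / 2; pG <- g / 2; pT <- (1 - g) / 2
  # rows: current base A,C,G,T per sequence; C row depleted in C->G
  normC <- 1 - pG * (1 - depletion)
  # cumulative transition probs, (4*n) x 3 matrix; row (b-1)*n + i is the
  # cumulative distribution of the next base given current base b in seq i
  cum <- matrix(0, 4L * n, 3L)
  for (b in 1:4) {
    rows <- (b - 1L) * n + seq_len(n)
    if (b == 2L) {  # from C
      cum[rows, 1] <- pA / normC
      cum[rows, 2] <- (pA + pC) / normC
      cum[rows, 3] <- (pA + pC + pG * depletion) / normC
    } else {
      cum[rows, 1] <- pA
      cum[rows, 2] <- pA + pC
      cum[rows, 3] <- pA + pC + pG
    }
  }
  out <- matrix(0L, n, window)
  u <- stats::runif(n)
  out[, 1] <- 1L + (u > pA) + (u > pA + pC) + (u > pA + pC + pG)
  for (j in seq_len(window)[-1]) {
    rows <- (out[, j - 1L] - 1L) * n + seq_len(n)
    u <- stats::runif(n)
    out[, j] <- 1L + (u > cum[rows, 1]) + (u > cum[rows, 2]) +
      (u > cum[rows, 3])
  }
  apply(matrix(bases[out], n, window), 1, paste, collapse = "")
}

#' GC propensity of a node
#'
#' \code{clamp(gc_base_type + gc_degree_slope * (degree - 1), 0.05, 0.95)}.
#'
#' @param node_type "promoter" or "enhancer".
#' @param degree Node degree (>= 1).
#' @param config A \code{synthetic_config}.
#' @return Numeric propensity in [0.05, 0.95].
#' @export
gc_propensity <- function(node_type, degree, config) {
  base <- ifelse(node_type == "promoter", config$gc_base_promoter,
                 config$gc_base_enhancer)
  pmin(pmax(base + config$gc_degree_slope * (degree - 1), 0.05), 0.95)
}

#' Generate one synthetic regulatory sequence
#'
#' A first-order Markov chain over A,C,G,T whose stationary GC propensity
#' depends on node type and degree, with the C->G (CpG) transition
#' probability multiplied by the type's depletion factor. Deterministic
#' given the config seed and node index.
#'
#' @param node_type "promoter" or "enhancer".
#' @param degree Node degree (>= 1).
#' @param config A \code{synthetic_config}.
#' @param node_index Integer distinguishing nodes of the same type and
#'   degree (default 1).
#' @return A nucleotide string of length \code{config$window}.
#' @export
generate_sequence <- function(node_type, degree, config, node_index = 1L) {
  if (degree < 1L) stop("degree must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  # multiplicative-hash mix of the node index into the substream seed
  set.seed(as.integer((.substream(config$seed, "sequences") +
                         node_index * 2654435761) %% 2147483647))
  g <- gc_propensity(node_type, degree, config)
  depl <- if (node_type == "promoter") config$cpg_depletion_promoter
          else config$cpg_depletion_enhancer
  .markov_seqs(1L, g, depl, config$window)
}

#' Generate a full synthetic dataset
#'
#' Builds the network, one synthetic "chromosome" per node (length
#' \code{window}, the node's standardized region spanning it exactly), and
#' the per-node truth table. When \code{dir} is given, writes the
#' canonical \code{generic_tsv} interaction table, the FASTA genome and
#' the truth table so the pipeline can be driven from files end to end.
#'
#' @param config A \code{synthetic_config}.
#' @param dir Optional output directory (created if needed).
#' @return A list: \code{interactions} (an \code{interaction_table}),
#'   \code{genome} (\code{DNAStringSet}), \code{nodes} (node table with
#'   realized degrees), \code{truth} (data.frame \code{node_id, node_type,
#'   degree, g}), \code{network}, \code{config}, and -- when \code{dir} is
#'   given -- \code{paths}.
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  gn <- generate_network(config)
  net <- gn$network
  w <- config$window
  # realized degrees (may differ from targets if duplicate edges dropped);
  # isolated nodes are omitted -- every emitted node has degree >= 1
  nodes <- data.frame(
    node_id = c(names(net$promoter_degree), names(net$enhancer_degree)),
    node_type = rep(c("promoter", "enhancer"),
                    c(length(net$promoter_degree),
                      length(net$enhancer_degree))),
    degree = c(as.integer(net$promoter_degree),
               as.integer(net$enhancer_degree)),
    stringsAsFactors = FALSE)
  nodes$chrom <- nodes$node_id
  nodes$anchor <- w %/% 2L
  nodes$strand <- ifelse(nodes$node_type == "promoter", "+", "unknown")

  g <- gc_propensity(nodes$node_type, nodes$degree, config)
  depl <- ifelse(nodes$node_type == "promoter",
                 config$cpg_depletion_promoter,
                 config$cpg_depletion_enhancer)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.substream(config$seed, "sequences"))
  seqs <- .markov_seqs(nrow(nodes), g, depl, w)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nodes$node_id

  interactions <- data.frame(
    promoter_id = net$edges$promoter_id,
    p_chrom = net$edges$promoter_id,
    p_anchor = w %/% 2L,
    p_strand = "+",
    enhancer_id = net$edges$enhancer_id,
    e_chrom = net$edges$enhancer_id,
    e_start = 0L,
    e_end = w,
    stringsAsFactors = FALSE)
  class(interactions) <- c("interaction_table", "data.frame")

  truth <- data.frame(node_id = nodes$node_id, node_type = nodes$node_type,
                      degree = nodes$degree, g = g,
                      stringsAsFactors = FALSE)
  out <- list(interactions = interactions, genome = genome, nodes = nodes,
              truth = truth, network = net, config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- data.frame(promoter_id = interactions$promoter_id,
                      p_chrom = interactions$p_chrom,
                      p_tss = interactions$p_anchor + 1L,  # back to 1-based
                      p_strand = interactions$p_strand,
                      enhancer_id = interactions$enhancer_id,
                      e_chrom = interactions$e_chrom,
                      e_start = interactions$e_start + 1L,
                      e_end = interactions$e_end,
                      stringsAsFactors = FALSE)
    paths <- list(interactions = file.path(dir, "interactions.tsv"),
                  genome = file.path(dir, "genome.fa"),
                  truth = file.path(dir, "truth.tsv"))
    write_tsv(tsv, paths$interactions)
    Biostrings::writeXStringSet(genome, paths$genome)
    write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}
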