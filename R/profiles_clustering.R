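#' Per-k-mer average-count profiles as a function of node degree
#'
#' For each k-mer, the mean count over all nodes of the given type at each
#' degree 1..D. Degrees with no node of that type yield NA columns (the
#' joint-profile step later restricts to degrees populated in both types).
#'
#' @param kmat K-mer count matrix, rows named by node id.
#' @param nodes Node table with \code{node_id, node_type, degree}.
#' @param type Node type to profile.
#' @param D Maximum degree (default 10).
#' @return A list of class \code{degree_profile}: \code{values} (matrix
#'   k-mers x degrees 1..D), \code{n_nodes} (integer per degree),
#'   \code{type}.
#' @export
degree_profiles <- function(kmat, nodes, type, D = 10L) {
  D <- as.integer(D)
  if (D < 1L) stop("D must be >= 1")
  idx <- match(rownames(kmat), nodes$node_id)
  if (anyNA(idx)) stop("k-mer matrix rows missing from the node table")
  sel <- nodes$node_type[idx] == type
  deg <- nodes$degree[idx][sel]
  m <- kmat[sel, , drop = FALSE]
  values <- matrix(NA_real_, ncol(kmat), D,
                   dimnames = list(colnames(kmat), as.character(1:D)))
  n_nodes <- integer(D)
  for (d in 1:D) {
    at <- deg == d
    n_nodes[d] <- sum(at)
    if (n_nodes[d] > 0L)
      values[, d] <- colMeans(m[at, , drop = FALSE])
  }
  structure(list(values = values, n_nodes = n_nodes, type = type, D = D),
            class = "degree_profile")
}

#' Join promoter and enhancer profiles head to tail and center
#'
#' Concatenates, for each k-mer, its promoter profile then its enhancer
#' profile (length 2D for D degrees) and centers each joint profile by
#' subtracting its own mean, so the clustering sees the shape of the
#' degree dependence, not the k-mer's base abundance. Only degrees
#' populated in both node types are used; if any of 1..D is empty the run
#' reports it and restricts D.
#'
#' @param p,e \code{degree_profile} objects for promoters and enhancers
#'   over the same k-mer set and D.
#' @param center Subtract the per-profile mean (default TRUE).
#' @return A list of class \code{joint_profile}: \code{values} (matrix
#'   k-mers x 2D'), \code{D} (the possibly restricted degree count),
#'   \code{degrees} (the degrees used), \code{centered}.
#' @export
join_and_center <- function(p, e, center = TRUE) {
  if (!identical(rownames(p$values), rownames(e$values)))
    stop("profiles cover different k-mer sets")
  if (p$D != e$D) stop("profiles have different D")
  ok <- which(p$n_nodes > 0L & e$n_nodes > 0L)
  if (!length(ok)) stop("no degree populated in both node types")
  if (length(ok) < p$D)
    message("restricting joint profiles to degrees {",
            paste(ok, collapse = ","), "} populated in both types")
  joint <- cbind(p$values[, ok, drop = FALSE],
                 e$values[, ok, drop = FALSE])
  colnames(joint) <- c(paste0("p", ok), paste0("e", ok))
  if (center) joint <- joint - rowMeans(joint)
  structure(list(values = joint, D = length(ok), degrees = ok,
                 n_promoter = p$n_nodes[ok], n_enhancer = e$n_nodes[ok],
                 centered = center),
            class = "joint_profile")
}

#' K-medoids (PAM) clustering with random restarts
#'
#' Classical PAM (build + swap) on Euclidean distances via
#' \code{cluster::pam}, plus \code{restarts} runs from seeded random
#' initial medoids; the solution with the lowest total cost (sum of
#' distances of points to their medoid) is kept. Deterministic given
#' \code{seed}. Medoids are always members of the input set.
#'
#' @param x Numeric matrix, one point per row.
#' @param k Number of clusters (1 <= k <= number of distinct rows).
#' @param seed RNG seed for the random restarts.
#' @param restarts Number of random initializations tried in addition to
#'   the deterministic BUILD start (default 5).
#' @return A list of class \code{kmedoids_result}: \code{clustering}
#'   (integer vector, named by rownames), \code{medoid_ids} (row indices),
#'   \code{medoids} (matrix), \code{cost}.
#' @export
kmedoids <- function(x, k, seed = 1L, restarts = 5L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points")
  if (k == nrow(x)) {  # trivial solution: every point its own medoid
    cl <- seq_len(nrow(x))
    names(cl) <- rownames(x)
    return(structure(list(clustering = cl, medoid_ids = cl,
                          medoids = x, cost = 0),
                     class = "kmedoids_result"))
  }
  runs <- vector("list", restarts + 1L)
  runs[[1]] <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE,
                            keep.data = FALSE)
  if (restarts > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    for (r in seq_len(restarts)) {
      init <- sample.int(nrow(x), k)
      runs[[r + 1L]] <- cluster::pam(x, k, metric = "euclidean",
                                     medoids = init, keep.diss = FALSE,
                                     keep.data = FALSE)
    }
  }
  # total cost = sum of Euclidean distances of points to their medoid
  # (pam's $objective is the average, and we compare across restarts)
  costs <- vapply(runs, function(p)
    sum(sqrt(rowSums((x - x[p$id.med[p$clustering], , drop = FALSE])^2))),
    numeric(1))
  best <- runs[[which.min(costs)]]
  cl <- best$clustering
  names(cl) <- rownames(x)
  structure(list(clustering = cl,
                 medoid_ids = best$id.med,
                 medoids = x[best$id.med, , drop = FALSE],
                 cost = min(costs)),
            class = "kmedoids_result")
}

#' Select the number of clusters with the gap statistic
#'
#' Gap(k) = E*[log W_k] - log W_k, with W_k the within-cluster dispersion
#' of the k-medoids clustering and the expectation over \code{B} reference
#' sets drawn uniformly over the per-coordinate range of the data.
#' k is chosen by Tibshirani's rule: the smallest k with
#' Gap(k) >= Gap(k+1) - s_{k+1}. Deterministic given \code{seed}.
#'
#' @param x Numeric matrix of points.
#' @param k_max Largest k considered (clamped to n - 1 with a warning).
#' @param B Number of uniform reference samples (default 50, minimum 10).
#' @param seed RNG seed.
#' @param restarts Restarts passed to \code{\link{kmedoids}}.
#' @return A list: \code{k_selected}, \code{gap_curve} (data.frame
#'   \code{k, logW, E_logW, gap, SE}).
#' @export
gap_statistic_select <- function(x, k_max = 10L, B = 50L, seed = 1L,
                                 restarts = 2L) {
  x <- as.matrix(x)
  if (B < 10L) stop("B must be >= 10")
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1")
  if (k_max >= nrow(x)) {
    warning("k_max clamped to n - 1")
    k_max <- nrow(x) - 1L
  }
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cg <- cluster::clusGap(
    x,
    FUNcluster = function(x, k)
      list(cluster = if (k == 1L) rep(1L, nrow(x))
           else kmedoids(x, k, seed = seed, restarts = restarts)$clustering),
    K.max = max(k_max, 2L), B = B, spaceH0 = "original", verbose = FALSE)
  tab <- as.data.frame(cg$Tab)[seq_len(k_max), , drop = FALSE]
  k_sel <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  list(k_selected = as.integer(k_sel),
       gap_curve = data.frame(k = seq_len(k_max), logW = tab$logW,
                              E_logW = tab$E.logW, gap = tab$gap,
                              SE = tab$SE.sim))
}

#' Cluster joint profiles and annotate clusters by CpG content and trend
#'
#' Runs k-medoids on centered joint profiles at the given (or
#' gap-selected) k, then summarizes each cluster: members, CpG-containing
#' member count, AT-only/GC-only counts, median promoter-half and
#' enhancer-half profiles, and a monotonicity label per half (increasing /
#' decreasing / flat by the sign of the Spearman correlation of the median
#' half against degree, at threshold |rho| >= 0.5). The overall
#' \code{trend_label} of a cluster averages the two within-half Spearman
#' correlations, computed only over degrees with at least
#' \code{min_cell_n} nodes of both types so that medians of sparsely
#' populated degrees do not swamp the trend with noise.
#'
#' @param joint A \code{joint_profile}.
#' @param k Number of clusters; if NULL it is selected by
#'   \code{\link{gap_statistic_select}}.
#' @param seed,restarts,k_max,B Clustering/model-selection controls.
#' @param rho_threshold Monotonicity threshold on |rho| (default 0.5).
#' @param min_cell_n Minimum nodes per degree cell (both types) for a
#'   degree to enter the trend label (default 5; all degrees are used
#'   when fewer than 3 qualify).
#' @return A list of class \code{profile_clustering}: \code{clustering},
#'   \code{k}, \code{gap} (NULL when k was given), \code{summary}
#'   (per-cluster data.frame), \code{medians} (list of per-cluster median
#'   promoter/enhancer half profiles).
#' @export
cluster_joint_profiles <- function(joint, k = NULL, seed = 1L,
                                   restarts = 5L, k_max = 10L, B = 50L,
                                   rho_threshold = 0.5, min_cell_n = 5L) {
  x <- joint$values
  gap <- NULL
  if (is.null(k)) {
    gap <- gap_statistic_select(x, k_max = k_max, B = B, seed = seed,
                                restarts = min(restarts, 2L))
    k <- gap$k_selected
  }
  km <- kmedoids(x, k, seed = seed, restarts = restarts)
  D <- joint$D
  cpg <- cpg_kmer_set(nchar(rownames(x)[1]))
  half_label <- function(v) {
    if (length(unique(v)) == 1L) return("flat")
    rho <- suppressWarnings(
      stats::cor(v, seq_along(v), method = "spearman"))
    if (is.na(rho) || abs(rho) < rho_threshold) "flat"
    else if (rho > 0) "increasing" else "decreasing"
  }
  # degrees solid enough (>= min_cell_n nodes in both types) to carry
  # the cluster-level trend label; fall back to all degrees when the
  # joint profile carries no cell sizes or too few degrees qualify
  ok <- if (!is.null(joint$n_promoter))
    joint$n_promoter >= min_cell_n & joint$n_enhancer >= min_cell_n
  else rep(TRUE, D)
  if (sum(ok) < 3L) ok <- rep(TRUE, D)
  half_rho <- function(v) {
    if (length(unique(v[ok])) == 1L) return(0)
    r <- suppressWarnings(
      stats::cor(v[ok], joint$degrees[ok], method = "spearman"))
    if (is.na(r)) 0 else r
  }
  joint_label <- function(med_p, med_e) {
    r <- mean(c(half_rho(med_p), half_rho(med_e)))
    if (abs(r) < rho_threshold) "flat"
    else if (r > 0) "increasing" else "decreasing"
  }
  summ <- do.call(rbind, lapply(seq_len(k), function(cl) {
    members <- rownames(x)[km$clustering == cl]
    sub <- x[km$clustering == cl, , drop = FALSE]
    med_p <- apply(sub[, seq_len(D), drop = FALSE], 2, stats::median)
    med_e <- apply(sub[, D + seq_len(D), drop = FALSE], 2, stats::median)
    base <- vapply(strsplit(members, ""), function(b)
      paste(sort(unique(b)), collapse = ""), character(1))
    data.frame(cluster = cl,
               n_members = length(members),
               n_cpg = sum(members %in% cpg),
               n_gc_only = sum(base %in% c("C", "G", "CG")),
               n_at_only = sum(base %in% c("A", "T", "AT")),
               promoter_label = half_label(med_p),
               enhancer_label = half_label(med_e),
               trend_label = joint_label(med_p, med_e),
               stringsAsFactors = FALSE)
  }))
  medians <- lapply(seq_len(k), function(cl) {
    sub <- x[km$clustering == cl, , drop = FALSE]
    list(promoter = apply(sub[, seq_len(D), drop = FALSE], 2, stats::median),
         enhancer = apply(sub[, D + seq_len(D), drop = FALSE], 2,
                          stats::median))
  })
  structure(list(clustering = km$clustering, k = k, gap = gap,
                 cost = km$cost, summary = summ, medians = medians),
            class = "profile_clustering")
}

#' CpG enrichment of increasing vs decreasing clusters
#'
#' One-sided Fisher exact test on the 2x2 table of k-mer membership
#' (increasing clusters vs decreasing clusters) against CpG content,
#' testing whether clusters whose median joint profiles increase with the
#' node degree are enriched in CpG-containing k-mers relative to clusters
#' whose median joint profiles decrease. The cluster trend is the
#' \code{trend_label} of the summary: the Spearman sign of the full joint
#' median profile against degree, which pools the promoter and enhancer
#' halves and so is robust to noise in sparsely populated degrees of one
#' type.
#'
#' @param clustering A \code{profile_clustering}.
#' @return A list: \code{table} (2x2), \code{p_value}, \code{odds_ratio},
#'   \code{increasing_clusters}, \code{decreasing_clusters}.
#' @export
cluster_cpg_enrichment <- function(clustering) {
  s <- clustering$summary
  inc <- s$cluster[s$trend_label == "increasing"]
  dec <- s$cluster[s$trend_label == "decreasing"]
  if (!length(inc) || !length(dec))
    stop("need at least one increasing and one decreasing cluster")
  cl <- clustering$clustering
  cpg <- cpg_kmer_set(nchar(names(cl)[1]))
  in_inc <- cl %in% inc
  in_dec <- cl %in% dec
  keep <- in_inc | in_dec
  tab <- table(group = factor(ifelse(in_inc[keep], "increasing",
                                     "decreasing"),
                              levels = c("increasing", "decreasing")),
               cpg = factor(names(cl)[keep] %in% cpg,
                            levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       increasing_clusters = inc, decreasing_clusters = dec)
}
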