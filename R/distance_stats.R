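#' Euclidean k-mer distance between two count vectors
#'
#' @param a,b Numeric vectors of equal length (256 coordinates for k = 4).
#' @return Nonnegative real; zero iff the vectors are equal.
#' @export
kmer_distance <- function(a, b) {
  if (length(a) != length(b)) stop("k-mer vectors differ in length")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' K-mer distances along every network edge
#'
#' @param network A \code{pe_network} whose node ids all have rows in
#'   \code{kmat}.
#' @param kmat K-mer count matrix with rownames = node ids.
#' @return Numeric vector parallel to \code{network$edges}.
#' @export
edge_kmer_distances <- function(network, kmat) {
  pi <- match(network$edges$promoter_id, rownames(kmat))
  ei <- match(network$edges$enhancer_id, rownames(kmat))
  if (anyNA(pi) || anyNA(ei))
    stop("network nodes missing from the k-mer matrix; prune_network first")
  sqrt(rowSums((kmat[pi, , drop = FALSE] - kmat[ei, , drop = FALSE])^2))
}

#' Local average k-mer distance (lakd) of every node
#'
#' For each node, the arithmetic mean of the Euclidean k-mer distances
#' over all its incident promoter-enhancer edges: for a promoter, its
#' average distance to the enhancers it interacts with, and conversely
#' for an enhancer. A degree-1 node's lakd is its distance to its single
#' partner.
#'
#' @param network A \code{pe_network}; nodes without k-mer vectors must be
#'   pruned away first (\code{\link{prune_network}}).
#' @param kmat K-mer count matrix with rownames = node ids.
#' @return A data.frame with \code{node_id, node_type, degree, lakd}, one
#'   row per network node.
#' @export
lakd <- function(network, kmat) {
  d <- edge_kmer_distances(network, kmat)
  pm <- tapply(d, network$edges$promoter_id, mean)
  em <- tapply(d, network$edges$enhancer_id, mean)
  out <- rbind(
    data.frame(node_id = names(pm), node_type = "promoter",
               degree = as.integer(network$promoter_degree[names(pm)]),
               lakd = as.numeric(pm), stringsAsFactors = FALSE),
    data.frame(node_id = names(em), node_type = "enhancer",
               degree = as.integer(network$enhancer_degree[names(em)]),
               lakd = as.numeric(em), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_x - ECDF_y|, with the asymptotic p-value at effective
#' sample size n_x n_y / (n_x + n_y); appropriate for the large samples
#' this pipeline produces.
#'
#' @param x,y Numeric samples of size >= 2.
#' @return A list: \code{D}, \code{p_value}.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples must have size >= 2")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Degree trend of lakd within one node type
#'
#' Ordinary least squares of lakd on node degree over individual nodes
#' (not per-degree means), plus the Spearman rank correlation (average
#' ranks for ties, asymptotic p), plus per-degree means for plotting.
#'
#' @param records lakd data.frame from \code{\link{lakd}}.
#' @param grouping Node type to analyze.
#' @param degree_range Optional \code{c(lo, hi)} restriction (default: all
#'   degrees).
#' @return A list of class \code{trend_result}: \code{grouping},
#'   \code{slope}, \code{slope_p}, \code{spearman_rho}, \code{spearman_p},
#'   \code{per_degree_means} (data.frame \code{degree, mean, n}).
#' @export
degree_trend <- function(records, grouping = c("promoter", "enhancer"),
                         degree_range = NULL) {
  grouping <- match.arg(grouping)
  r <- records[records$node_type == grouping, , drop = FALSE]
  if (!is.null(degree_range))
    r <- r[r$degree >= degree_range[1] & r$degree <= degree_range[2], ,
           drop = FALSE]
  if (length(unique(r$degree)) < 2L)
    stop("degree is constant within the group")
  if (length(unique(r$degree)) < 3L && nrow(r) > 2L)
    stop("need at least 3 distinct degrees")
  fit <- stats::lm(lakd ~ degree, data = r)
  sm <- summary(fit)$coefficients
  sp <- suppressWarnings(
    stats::cor.test(r$lakd, r$degree, method = "spearman", exact = FALSE))
  pdm <- stats::aggregate(lakd ~ degree, data = r,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  per_degree <- data.frame(degree = pdm$degree,
                           mean = pdm$lakd[, "mean"],
                           n = as.integer(pdm$lakd[, "n"]))
  structure(list(grouping = grouping,
                 slope = unname(sm["degree", "Estimate"]),
                 slope_p = unname(sm["degree", "Pr(>|t|)"]),
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 per_degree_means = per_degree,
                 n = nrow(r)),
            class = "trend_result")
}

#' Composition-vs-degree trend table with fold changes
#'
#' For each composition metric (GG, CC, GC, CG counts and %GC): its
#' correlation with the node degree over individual nodes (Spearman by
#' default, Pearson by flag), the correlation p-value, the OLS slope of
#' the metric on degree, per-degree means, and the fold change
#' FC(d) = mean(d) / mean(1) relative to degree 1 (exactly 1 at degree 1).
#'
#' @param stats_df Data.frame from \code{\link{composition_stats}} carrying
#'   \code{node_type} and \code{degree}.
#' @param grouping Node type to analyze.
#' @param degree_range Optional \code{c(lo, hi)} restriction.
#' @param method Correlation type: \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @return A list of class \code{composition_trends}: \code{table}
#'   (data.frame \code{metric, correlation, p_value, slope}),
#'   \code{per_degree_means} and \code{fold_change} (matrices metric x
#'   degree), \code{grouping}, \code{method}.
#' @export
composition_trends <- function(stats_df,
                               grouping = c("promoter", "enhancer"),
                               degree_range = NULL,
                               method = c("spearman", "pearson")) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  r <- stats_df[stats_df$node_type == grouping, , drop = FALSE]
  if (!is.null(degree_range))
    r <- r[r$degree >= degree_range[1] & r$degree <= degree_range[2], ,
           drop = FALSE]
  if (!any(r$degree == 1L))
    stop("no degree-1 nodes: fold change relative to degree 1 is undefined")
  metrics <- c("GG", "CC", "GC", "CG", "%GC")
  cols <- c("GG", "CC", "GC", "CG", "gc_percent")
  degs <- sort(unique(r$degree))
  tab <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    v <- r[[cols[i]]]
    ct <- suppressWarnings(
      stats::cor.test(v, r$degree, method = method, exact = FALSE))
    sl <- stats::lm(v ~ degree, data = data.frame(v = v,
                                                  degree = r$degree))
    data.frame(metric = metrics[i],
               correlation = unname(ct$estimate),
               p_value = ct$p.value,
               slope = unname(stats::coef(sl)["degree"]),
               stringsAsFactors = FALSE)
  }))
  pdm <- sapply(cols, function(cn)
    tapply(r[[cn]], factor(r$degree, levels = degs), mean))
  pdm <- t(pdm)  # metric x degree
  rownames(pdm) <- metrics
  colnames(pdm) <- as.character(degs)
  fc <- pdm / pdm[, "1"]
  structure(list(table = tab, per_degree_means = pdm, fold_change = fc,
                 grouping = grouping, method = method, n = nrow(r)),
            class = "composition_trends")
}

#' Distribution report for lakd grouped by node type
#'
#' Emits per-type lakd summaries, the two-sample KS comparison of the
#' promoter-grouped vs enhancer-grouped distributions, and the direction
#' of the shift (which node type is locally more similar to its partners,
#' i.e. has the smaller mean lakd).
#'
#' @param records lakd data.frame from \code{\link{lakd}}.
#' @return A list: \code{mean_promoter}, \code{mean_enhancer}, \code{ks}
#'   (list D, p_value), \code{shifted_left} ("promoter"/"enhancer"),
#'   \code{values} (per-type lakd vectors).
#' @export
lakd_distribution_report <- function(records) {
  p <- records$lakd[records$node_type == "promoter"]
  e <- records$lakd[records$node_type == "enhancer"]
  if (!length(p) || !length(e))
    stop("both node types must be present")
  ks <- ks_two_sample(p, e)
  list(mean_promoter = mean(p), mean_enhancer = mean(e), ks = ks,
       shifted_left = if (mean(p) < mean(e)) "promoter" else "enhancer",
       values = list(promoter = p, enhancer = e))
}
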