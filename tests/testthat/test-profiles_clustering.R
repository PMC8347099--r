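make_kmat <- function(counts, ids) {
  m <- matrix(counts, nrow = length(ids), byrow = TRUE)
  rownames(m) <- ids
  colnames(m) <- kmer_names(1)[seq_len(ncol(m))]
  m
}

test_that("degree_profiles are per-degree group means", {
  nodes <- data.frame(node_id = c("a", "b", "c"),
                      node_type = "promoter",
                      degree = c(3L, 3L, 1L))
  kmat <- make_kmat(c(2, 0, 0, 0,
                      4, 0, 0, 0,
                      1, 1, 1, 1), c("a", "b", "c"))
  prof <- degree_profiles(kmat, nodes, "promoter", D = 5)
  expect_equal(unname(prof$values["A", "3"]), 3.0)
  expect_equal(unname(prof$values["A", "1"]), 1.0)
  expect_true(all(is.na(prof$values[, c("2", "4", "5")])))
  expect_equal(prof$n_nodes, c(1L, 0L, 2L, 0L, 0L))
  expect_error(degree_profiles(kmat, nodes, "promoter", D = 0), "D must")
})

test_that("degree_profiles match a group-by oracle on the shared dataset", {
  pipe <- shared_pipeline()
  prof <- degree_profiles(pipe$kmat, pipe$nodes, "enhancer", D = 4)
  deg <- pipe$nodes$degree[match(rownames(pipe$kmat), pipe$nodes$node_id)]
  is_e <- pipe$nodes$node_type[match(rownames(pipe$kmat),
                                     pipe$nodes$node_id)] == "enhancer"
  for (d in 1:4) {
    sel <- is_e & deg == d
    expect_equal(unname(prof$values[, as.character(d)]),
                 unname(colSums(pipe$kmat[sel, , drop = FALSE]) / sum(sel)))
  }
})

test_that("join_and_center concatenates promoter-first and centers to zero mean", {
  mk_prof <- function(vals, type) {
    v <- matrix(rep(vals, each = 2), nrow = 2, byrow = FALSE)
    rownames(v) <- c("AA", "AC"); colnames(v) <- as.character(1:3)
    structure(list(values = v, n_nodes = rep(1L, 3), type = type, D = 3L),
              class = "degree_profile")
  }
  # constant c in both halves -> centered all zeros
  jp <- join_and_center(mk_prof(c(5, 5, 5), "promoter"),
                        mk_prof(c(5, 5, 5), "enhancer"))
  expect_true(all(jp$values == 0))
  # +1 / -1 halves are already centered
  jp2 <- join_and_center(mk_prof(c(1, 1, 1), "promoter"),
                         mk_prof(c(-1, -1, -1), "enhancer"))
  expect_equal(unname(jp2$values[1, ]), c(1, 1, 1, -1, -1, -1))
  expect_lt(max(abs(rowMeans(jp2$values))), 1e-12)

  bad <- mk_prof(c(1, 2, 3), "enhancer")
  rownames(bad$values) <- c("GG", "GT")
  expect_error(join_and_center(mk_prof(c(1, 2, 3), "promoter"), bad),
               "different k-mer sets")
})

test_that("joint profiles restrict to degrees populated in both types", {
  p <- structure(list(values = matrix(1:6, 1, 6,
                                      dimnames = list("AA", 1:6)),
                      n_nodes = c(1L, 1L, 0L, 1L, 1L, 1L),
                      type = "promoter", D = 6L),
                 class = "degree_profile")
  e <- structure(list(values = matrix(6:1, 1, 6,
                                      dimnames = list("AA", 1:6)),
                      n_nodes = c(1L, 1L, 1L, 1L, 0L, 1L),
                      type = "enhancer", D = 6L),
                 class = "degree_profile")
  expect_message(jp <- join_and_center(p, e), "restricting")
  expect_equal(jp$degrees, c(1L, 2L, 4L, 6L))
  expect_equal(ncol(jp$values), 8L)
})

test_that("kmedoids returns member medoids, zero cost at k = n, and is deterministic", {
  set.seed(4)
  x <- matrix(rnorm(24), 12, 2)
  rownames(x) <- letters[1:12]
  full <- kmedoids(x, 12, seed = 1)
  expect_equal(full$cost, 0)
  expect_equal(length(unique(full$clustering)), 12L)

  r1 <- kmedoids(x, 3, seed = 5, restarts = 4)
  r2 <- kmedoids(x, 3, seed = 5, restarts = 4)
  expect_identical(r1$clustering, r2$clustering)
  expect_true(all(r1$medoid_ids %in% seq_len(nrow(x))))
  expect_error(kmedoids(x, 0), "k must")
  expect_error(kmedoids(x, 13), "exceeds")
})

test_that("kmedoids matches exhaustive medoid search on small instances", {
  set.seed(14)
  for (i in 1:5) {
    x <- rbind(matrix(rnorm(12, 0, 0.3), 6, 2),
               matrix(rnorm(12, 6, 0.3), 6, 2))
    km <- kmedoids(x, 2, seed = i, restarts = 3)
    expect_equal(km$cost, oracle_kmedoids_cost(x, 2), tolerance = 1e-9)
    # two well-separated clouds -> nearest-cloud labeling
    expect_equal(length(unique(km$clustering[1:6])), 1L)
    expect_equal(length(unique(km$clustering[7:12])), 1L)
    expect_false(km$clustering[1] == km$clustering[7])
  }
})

test_that("gap statistic recovers planted structure and is deterministic", {
  gen3 <- function(seed) {
    set.seed(seed)
    rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
          matrix(rnorm(40, 6, 0.5), 20, 2),
          matrix(rnorm(40, c(0, 12), 0.5), 20, 2))
  }
  hits <- sum(vapply(1:20, function(s)
    gap_statistic_select(gen3(s), k_max = 6, B = 20, seed = s,
                         restarts = 1)$k_selected == 3L, logical(1)))
  expect_gte(hits, 19)  # >= 95% of 20 seeds

  # single tight cluster -> k = 1
  set.seed(2)
  tight <- matrix(rnorm(60, 0, 0.1), 30, 2)
  expect_equal(gap_statistic_select(tight, k_max = 5, B = 20,
                                    seed = 3)$k_selected, 1L)

  g1 <- gap_statistic_select(gen3(99), k_max = 5, B = 15, seed = 8)
  g2 <- gap_statistic_select(gen3(99), k_max = 5, B = 15, seed = 8)
  expect_identical(g1$gap_curve, g2$gap_curve)
  expect_warning(gap_statistic_select(tight[1:4, ], k_max = 10, B = 10,
                                      seed = 1), "clamped")
})

test_that("cluster annotation labels injected monotone trends and CpG content", {
  # build joint profiles with known slope signs for a handful of 4-mers
  D <- 5
  kms <- c("ACGT", "CCGG", "TCGA", "AAAA", "TTTT", "ATAT")
  up <- seq(-2, 2, length.out = D)
  vals <- rbind(c(up, up), c(up, up), c(up, up),
                c(-up, -up), c(-up, -up), c(rep(0, D), rep(0, D)))
  set.seed(6)
  vals[1:5, ] <- vals[1:5, ] + rnorm(5 * 2 * D, 0, 1e-3)  # flat row exact
  vals <- vals - rowMeans(vals)
  rownames(vals) <- kms
  joint <- structure(list(values = vals, D = D, degrees = 1:D,
                          centered = TRUE), class = "joint_profile")
  cl <- cluster_joint_profiles(joint, k = 3, seed = 2)
  s <- cl$summary
  lab_of <- function(km) {
    cid <- cl$clustering[km]
    s[s$cluster == cid, c("promoter_label", "enhancer_label")]
  }
  expect_equal(unlist(lab_of("ACGT"), use.names = FALSE),
               c("increasing", "increasing"))
  expect_equal(unlist(lab_of("AAAA"), use.names = FALSE),
               c("decreasing", "decreasing"))
  expect_equal(unlist(lab_of("ATAT"), use.names = FALSE), c("flat", "flat"))

  # cluster of all-CpG members has CpG count == size
  inc <- s[s$promoter_label == "increasing", ]
  expect_equal(inc$n_cpg, inc$n_members)
})
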