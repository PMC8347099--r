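test_that("generate_network is deterministic and degree-exact", {
  cfg <- synthetic_config(n_promoters = 50, n_enhancers = 220, seed = 5)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(g1$network$edges, g2$network$edges)
  # handshake on both sides
  expect_equal(sum(g1$network$promoter_degree), nrow(g1$network$edges))
  expect_equal(sum(g1$network$enhancer_degree), nrow(g1$network$edges))
  # simple graph: no duplicate edges
  key <- paste(g1$network$edges$promoter_id, g1$network$edges$enhancer_id)
  expect_false(any(duplicated(key)))
})

test_that("degenerate config gives a perfect matching of degree-1 nodes", {
  cfg <- synthetic_config(n_promoters = 40, n_enhancers = 40,
                          promoter_degree_mean = 1e-6,
                          enhancer_p1 = 1, seed = 3)
  g <- generate_network(cfg)
  expect_true(all(g$network$promoter_degree == 1L))
  expect_true(all(g$network$enhancer_degree == 1L))
  expect_equal(nrow(g$network$edges), 40L)
})

test_that("realized degree histograms follow the configured laws", {
  # sizes chosen so the two sides' expected stub totals agree (the
  # zero-truncated NB mean is 6.4, so 1500 * 6.4 vs 7200 * 4/3), keeping
  # the reconciliation residual negligible
  cfg <- synthetic_config(n_promoters = 1500, n_enhancers = 7200, seed = 11)
  g <- generate_network(cfg)
  # promoter side: zero-truncated NB; chi-square goodness of fit with
  # tail binning at expected count >= 5
  pd <- as.integer(g$target_degrees$degree[
    g$target_degrees$node_type == "promoter"])
  pmf <- function(d) dnbinom(d, mu = cfg$promoter_degree_mean,
                             size = cfg$promoter_degree_dispersion) /
    (1 - dnbinom(0, mu = cfg$promoter_degree_mean,
                 size = cfg$promoter_degree_dispersion))
  hi <- max(pd)
  p <- vapply(1:hi, pmf, numeric(1))
  p <- c(p, 1 - sum(p))  # tail bin
  obs <- c(tabulate(pd, hi), 0)
  keep <- p * length(pd) >= 5
  chi <- suppressWarnings(chisq.test(
    c(obs[keep], sum(obs[!keep])),
    p = c(p[keep], sum(p[!keep])), rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)

  # enhancer side: P(1) = p1, geometric tail
  ed <- as.integer(g$target_degrees$degree[
    g$target_degrees$node_type == "enhancer"])
  epmf <- function(d) if (d == 1) cfg$enhancer_p1 else
    (1 - cfg$enhancer_p1) * dgeom(d - 2, cfg$enhancer_geom_p)
  hi <- max(ed)
  p <- vapply(1:hi, epmf, numeric(1))
  obs <- tabulate(ed, hi)
  keep <- p * length(ed) >= 5
  chi2 <- suppressWarnings(chisq.test(
    c(obs[keep], sum(obs[!keep])),
    p = c(p[keep], 1 - sum(p[keep])), rescale.p = TRUE))
  expect_gt(chi2$p.value, 0.01)
})

test_that("markov sequences respect CpG depletion and GC propensity", {
  cfg <- synthetic_config(seed = 9, cpg_depletion_promoter = 1,
                          gc_base_promoter = 0.5, gc_degree_slope = 0)
  # symmetric chain: CG and GC counts agree within 3 SD over 200 sequences
  seqs <- vapply(1:200, function(i)
    generate_sequence("promoter", 1, cfg, node_index = i), character(1))
  cs <- composition_stats(seqs)
  dif <- cs$CG - cs$GC
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(nrow(cs)))

  # depletion ~ 0 removes the CpG transition entirely
  cfg0 <- synthetic_config(seed = 9, cpg_depletion_promoter = 1e-12)
  s0 <- generate_sequence("promoter", 3, cfg0)
  expect_equal(composition_stats(s0)$CG, 0L)

  # determinism given seed + node index
  expect_identical(generate_sequence("enhancer", 2, cfg, node_index = 4),
                   generate_sequence("enhancer", 2, cfg, node_index = 4))

  # gc propensity clamps and slopes
  expect_equal(gc_propensity("promoter", 1, cfg), 0.5)
  cfgs <- synthetic_config(gc_degree_slope = 0.01)
  expect_equal(gc_propensity("enhancer", 11, cfgs), 0.55)
  expect_equal(gc_propensity("promoter", 1000, cfgs), 0.95)
})

test_that("zero GC-degree slope yields no degree-GC correlation", {
  ds <- generate_dataset(synthetic_config(seed = 13, gc_degree_slope = 0))
  cs <- composition_stats(ds$genome, nodes = ds$nodes)
  e <- cs[cs$node_type == "enhancer", ]
  rho <- suppressWarnings(cor(e$gc_percent, e$degree, method = "spearman"))
  expect_lt(abs(rho), 0.05)
})

test_that("generate_dataset output is pipeline-consumable and truthful", {
  dir <- file.path(tempdir(), "synthds")
  ds <- generate_dataset(synthetic_config(n_promoters = 60,
                                          n_enhancers = 280, seed = 21),
                         dir = dir)
  # files round-trip through the readers
  tab <- read_interaction_table(ds$paths$interactions, "generic_tsv")
  expect_equal(nrow(tab), nrow(ds$interactions))
  genome <- read_genome(ds$paths$genome)
  expect_equal(length(genome), nrow(ds$nodes))

  pipe <- run_composition_pipeline(tab, genome, window = 1000)
  expect_equal(nrow(pipe$dropped), 0L)  # constructed in bounds
  expect_equal(nrow(pipe$nodes), nrow(ds$nodes))

  # truth g vs measured GC%: strong linear recovery
  cs <- pipe$composition
  tr <- ds$truth[match(cs$node_id, ds$truth$node_id), ]
  expect_gt(cor(cs$gc_percent, tr$g), 0.9)

  # promoters built more GC-rich than enhancers
  expect_gt(mean(cs$gc_percent[cs$node_type == "promoter"]),
            mean(cs$gc_percent[cs$node_type == "enhancer"]))
})

test_that("CpG-containing 4-mers are collectively depleted in enhancers", {
  pipe <- shared_pipeline()
  mp <- mean_count_by_type(pipe$kmat, pipe$nodes$node_type[
    match(rownames(pipe$kmat), pipe$nodes$node_id)], "promoter")
  me <- mean_count_by_type(pipe$kmat, pipe$nodes$node_type[
    match(rownames(pipe$kmat), pipe$nodes$node_id)], "enhancer")
  cpg <- cpg_kmer_set(4)
  # relative abundance of CpG k-mers vs all k-mers, promoter vs enhancer
  expect_gt(sum(mp[cpg]) / sum(mp), sum(me[cpg]) / sum(me))
  # and per-k-mer: most CpG 4-mers individually rarer in enhancers
  expect_gt(mean(mp[cpg] > me[cpg]), 0.9)
})
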