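# Shared synthetic dataset + pipeline, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(synthetic_config(seed = 42L))
  .fixture_env$ds
}

shared_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    ds <- shared_dataset()
    .fixture_env$pipe <- run_composition_pipeline(ds$interactions, ds$genome)
  }
  .fixture_env$pipe
}

shared_lakd <- function() {
  if (is.null(.fixture_env$lakd)) {
    p <- shared_pipeline()
    .fixture_env$lakd <- lakd(p$network, p$kmat)
  }
  .fixture_env$lakd
}

# a tiny hand-built interaction TSV: 2 promoters, 3 enhancers, one
# duplicated pair
write_tiny_interactions <- function(path, dup = TRUE) {
  rows <- data.frame(
    promoter_id = c("P1", "P1", "P2", if (dup) "P1"),
    p_chrom = "chr1",
    p_tss = c(10000L, 10000L, 20000L, if (dup) 10000L),
    p_strand = "+",
    enhancer_id = c("E1", "E2", "E3", if (dup) "E1"),
    e_chrom = "chr1",
    e_start = c(30001L, 40001L, 50001L, if (dup) 30001L),
    e_end = c(31000L, 42000L, 50900L, if (dup) 31000L),
    stringsAsFactors = FALSE)
  write_tsv(rows, path)
  path
}
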