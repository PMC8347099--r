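# Brute-force oracles, kept independent of the package implementation.

# sliding-window k-mer counter: walks every window, skips any with non-ACGT
oracle_count_kmers <- function(seq, k) {
  km <- character(0)
  for (i in seq_len(nchar(seq) - k + 1)) km <- c(km, substr(seq, i, i + k - 1))
  km <- km[!grepl("[^ACGT]", km)]
  all_k <- ""
  for (i in seq_len(k))
    all_k <- as.vector(outer(all_k, c("A", "C", "G", "T"), paste0))
  all_k <- sort(all_k)
  counts <- integer(length(all_k))
  names(counts) <- all_k
  tb <- table(km)
  counts[names(tb)] <- as.integer(tb)
  counts
}

# count of length-k ACGT strings containing "CG", via the transfer
# recurrence for strings avoiding it (x = avoid & end in C, y = avoid &
# end in non-C)
oracle_n_cpg_kmers <- function(k) {
  if (k < 2) return(0L)
  x <- 1; y <- 3
  for (i in 2:k) {
    xn <- x + y
    yn <- 3 * y + 2 * x
    x <- xn; y <- yn
  }
  as.integer(4^k - (x + y))
}

# two-sample KS D by scanning every breakpoint
oracle_ks_D <- function(x, y) {
  br <- sort(unique(c(x, y)))
  max(abs(vapply(br, function(b) mean(x <= b) - mean(y <= b), numeric(1))))
}

# exhaustive k-medoids: try every medoid subset of size k, Euclidean cost
oracle_kmedoids_cost <- function(x, k) {
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  combs <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    cost <- sum(apply(dm[, combs[, j], drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
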