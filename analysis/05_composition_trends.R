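#!/usr/bin/env Rscript
# Stage 5: GC% and G/C-dinucleotide counts vs node degree.
#
# For each node type, the Spearman correlation (node-level), its p-value
# and the OLS slope of GG, CC, GC, CG counts and %GC on node degree,
# plus per-degree means and the fold change relative to degree 1 -- the
# trend table and fold-change profiles of the composition analysis.

suppressMessages(library(kmernet))

pipe <- readRDS("scratch/pipe.rds")

rows <- list()
for (type in c("promoter", "enhancer")) {
  ct <- composition_trends(pipe$composition, type)
  cat("\n", type, "s (n = ", ct$n, ", ", ct$method, "):\n", sep = "")
  print(ct$table, row.names = FALSE)
  fc <- data.frame(metric = rownames(ct$fold_change),
                   node_type = type, ct$fold_change,
                   check.names = FALSE)
  write_tsv(fc, sprintf("results/fold_change_%s.tsv", type))
  rows[[type]] <- data.frame(node_type = type, ct$table)
}
write_tsv(do.call(rbind, rows), "results/composition_trend_table.tsv")
cat("\nwrote results/composition_trend_table.tsv and fold-change tables\n")
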