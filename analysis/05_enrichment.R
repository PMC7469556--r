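#!/usr/bin/env Rscript
# Over-representation analysis of the prioritized hub genes against the
# gene-set collection (one set per planted block + decoys), reporting the
# size / expect / ratio / hypergeometric p / BH-FDR columns.
# Writes results/enrichment.tsv.

library(adipolink)

sets <- read_gene_sets("results/data/gene_sets.gmt")
hubs <- readLines("results/prioritized_genes.txt")

enr <- ora(hubs, sets)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("tested %d sets with %d reference-mapped input genes\n",
            nrow(enr), attr(enr, "n_input")))
cat("top rows (name, size, overlap, expect, ratio, p, fdr):\n")
print(head(enr[, c("name", "size", "overlap", "expect", "ratio", "p", "fdr")],
           5), row.names = FALSE, digits = 4)
cat(sprintf("%d set(s) significant at FDR < 0.05\n", sum(enr$fdr < 0.05)))
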