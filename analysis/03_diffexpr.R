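#!/usr/bin/env Rscript
# Non-specific filtering, empirical-Bayes moderated-t differential
# expression (case vs control) and intersection with the disease panel.
# Writes results/de_results.tsv, results/degs.tsv, results/disease_degs.tsv.

library(adipolink)

x <- read_expression_matrix("results/data/expression.tsv")
samples <- read_sample_table("results/data/samples.tsv")
panel <- read_gene_list("results/data/disease_genes.txt")

params <- diffexpr_params()
res <- moderated_t(nonspecific_filter(x, params), samples, params)
degs <- select_degs(res, params$alpha)
lipo <- intersect_disease_genes(degs, panel)

write.table(res, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(degs, "results/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene = c(lipo$up, lipo$down),
                       direction = rep(c("up", "down"),
                                       c(length(lipo$up), length(lipo$down)))),
            "results/disease_degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d of %d genes DE at p < %.2f (prior df d0 = %.1f)\n",
            nrow(degs), nrow(res), params$alpha, attr(res, "d0")))
cat(sprintf("disease-panel DEGs: %d up, %d down\n",
            lipo$counts[["up"]], lipo$counts[["down"]]))
cat("up:  ", paste(lipo$up, collapse = ", "), "\n")
cat("down:", paste(lipo$down, collapse = ", "), "\n")
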