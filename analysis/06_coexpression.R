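#!/usr/bin/env Rscript
# Weighted co-expression analysis of the disease-panel submatrix, run
# separately in controls and cases (beta = 15 soft threshold, TOM,
# static tree cut, module eigengenes, module-trait Pearson correlations).
# Writes results/modules_<group>.tsv and results/module_trait_<group>.tsv.

library(adipolink)

x <- read_expression_matrix("results/data/expression.tsv")
samples <- read_sample_table("results/data/samples.tsv")
panel <- read_gene_list("results/data/disease_genes.txt")

for (grp in c("control", "case")) {
  res <- coexpression_group(x, samples, panel, grp)
  write.table(data.frame(gene = names(res$assignment),
                         module = unname(res$assignment)),
              sprintf("results/modules_%s.tsv", grp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$module_trait, sprintf("results/module_trait_%s.tsv", grp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- table(res$assignment)
  cat(sprintf("[%s] modules: %s | scale-free R^2 = %.2f\n", grp,
              paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "),
              res$scale_free$r_squared))
  sig <- res$module_trait[!is.na(res$module_trait$p) &
                            res$module_trait$p < 0.05, ]
  cat(sprintf("[%s] significant module-trait pairs (p < 0.05):\n", grp))
  print(sig[, c("module", "trait", "r", "p")], row.names = FALSE, digits = 3)
}
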