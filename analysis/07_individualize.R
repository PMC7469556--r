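#!/usr/bin/env Rscript
# Per-patient individualization: flag disease-panel genes deviating more
# than 2 control SDs from the control mean in each case sample, then the
# population frequency of flagged genes.
# Writes results/patient_flags.tsv and results/gene_frequencies.tsv.

library(adipolink)

x <- read_expression_matrix("results/data/expression.tsv")
samples <- read_sample_table("results/data/samples.tsv")
panel <- read_gene_list("results/data/disease_genes.txt")

params <- individualization_params(mode = "sd", threshold = 2)
env <- control_envelope(x, samples, panel, params$min_control_sd)
fl <- flag_patient_genes(x, samples, env, params)
fs <- frequency_summary(fl)

write.table(fl$flags, "results/patient_flags.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fs$frequency, "results/gene_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_cases <- sum(samples$group == "case")
cat(sprintf("%d of %d cases carry at least one flagged panel gene (mode %s, +/-%g)\n",
            fs$patients_with_any, n_cases, params$mode, params$threshold))
cat("most frequently flagged genes:\n")
print(head(fs$frequency, 8), row.names = FALSE)
per_patient_counts <- table(fl$flags$sample_id)
cat(sprintf("flags per flagged patient: median %g, range %d-%d\n",
            median(per_patient_counts), min(per_patient_counts),
            max(per_patient_counts)))
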