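#!/usr/bin/env Rscript
# Build the synthetic study cohort: 30 NGT controls + 30 T2D cases, 5000
# genes on log2 scale, a 138-gene lipodystrophy panel carrying 16 planted
# DEGs (7 up / 9 down) and two planted co-expression blocks coupled to
# Cell_size and LDL, a scale-free interactome seeded with the panel, and
# planted per-patient outlier genes in 25 of the 30 cases.
# Writes all five artifacts plus the truth record under results/data/.

library(adipolink)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
write_dataset(sim, "results/data")

cat(sprintf("cohort: %d genes x %d samples; disease panel %d genes\n",
            nrow(sim$expression), ncol(sim$expression),
            length(sim$truth$disease_genes)))
cat(sprintf("planted: %d DEGs (%d in the panel), %d blocks of %d, %d outlier cells\n",
            nrow(sim$truth$de_genes), sum(sim$truth$de_genes$is_disease),
            length(sim$truth$modules), cfg$module_size,
            nrow(sim$truth$outliers)))
cat("artifacts written to results/data/\n")
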