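# adipolink

Systems-level analysis linking a monogenic disease gene panel
(lipodystrophy genes) to case-control adipose-tissue transcriptomes.

Partial lipodystrophy — selective loss of peripheral subcutaneous fat with
severe insulin resistance — is monogenic; type 2 diabetes in "thin fat"
populations is polygenic but phenotypically convergent. `adipolink` asks
whether the expression of the known lipodystrophy genes misbehaves in the
peripheral adipose tissue of diabetics, and turns that question into a
six-stage pipeline for a 30 NGT + 30 T2D biopsy design:

1. **Trait comparisons** — Welch t-tests (`t = Δx̄/√(s₁²/n₁+s₂²/n₂)`,
   Welch–Satterthwaite df) of intermediate phenotypes per sex stratum,
   from raw vectors or from a published mean ± SD table.
2. **Differential expression** — non-specific filtering, then an
   empirical-Bayes moderated t: `s²post = (d₀s₀² + d_g s_g²)/(d₀+d_g)`,
   `t̃ = Δx̄/(s_post√(1/n₁+1/n₂))` on `d₀+d_g` df, with `d₀, s₀²` fitted by
   digamma/trigamma moment matching on `log s_g²`; DEGs at p < 0.05,
   intersected with the disease panel.
3. **Interactome** — the panel's first-degree neighbourhood in a
   protein-interaction network, DEG overlap, reduction to the
   disease-DEG neighbourhood, and hub prioritization as the union of the
   top-100 nodes by degree and by bottleneck centrality
   (`BN(v) = Σ_s 1[subtree of v in T_s > |T_s|/4]` over BFS shortest-path
   trees).
4. **ORA** — hypergeometric over-representation of the prioritized hubs:
   expect `nK/N`, ratio `k/expect`, `p = P(X ≥ k)`, BH-FDR.
5. **Co-expression** — WGCNA-style modules of the panel submatrix per
   group: `a_ij = |cor|^β` (β = 15), topological overlap, static tree cut,
   module eigengenes (first PC), eigengene–trait Pearson correlations.
6. **Individualization** — per-patient flags for panel genes outside the
   control envelope (±2 SD or ±2-fold on log2 scale), plus population
   frequencies.

A seeded synthetic-cohort generator with a full truth record
(`simulate_dataset()`) stands in for the original microarray series, so
every stage is validated by parameter recovery and calibration instead of
by downloads. See `vignettes/adipolink-methods.Rmd` for the models,
parameter rationale and limitations.

## Worked example

The repository is organised as an analysis workflow; the numbered scripts
under `analysis/` run the whole study on a synthetic cohort:

```sh
Rscript analysis/01_simulate.R 1      # cohort + truth -> results/data/
Rscript analysis/02_trait_tests.R
Rscript analysis/03_diffexpr.R
Rscript analysis/04_network.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_coexpression.R
Rscript analysis/07_individualize.R
```

Selected output from a run with seed 1:

```
male stratum: 8/21 printed p-values consistent with Welch recomputation
           trait p_printed        p
       Weight_kg    0.0400 0.040852
 Fasting_glucose    0.0006 0.000632
             HDL    0.9100 0.910057

373 of 5000 genes DE at p < 0.05 (prior df d0 = 4200.1)
disease-panel DEGs: 9 up, 11 down

interactome: 2691 nodes / 7083 edges (seed attrition 0)
DEG overlap: 193 of 373 DEGs (51.7%) inside the interactome
reduced disease-DEG neighbourhood: 455 nodes
prioritized hub union (top 100 by degree U top 100 by bottleneck): 116 genes

    name size overlap expect ratio         p       fdr
  block2   30      13  1.739 7.475 5.178e-10 1.139e-08
  block1   30      12  1.739 6.900 8.937e-09 9.831e-08

[case] modules: blue (26), grey (84), turquoise (28) | scale-free R^2 = 0.79
 turquoise Cell_size  0.593 0.000559

30 of 30 cases carry at least one flagged panel gene (mode sd, +/-2)
```

Reading it: the published male-stratum trait comparisons reproduce under
Welch recomputation (weight p = 0.041 prints as 0.04, and so on); the
planted disease-panel DEGs are recovered with a few chance extras at
p < 0.05; the two planted co-expression blocks surface as the turquoise
and blue modules and dominate the hub enrichment (ratio ≈ 7 at FDR
≪ 0.05), with the turquoise module tracking the trait its latent factor
was coupled to. With 138 panel genes and a ±2σ envelope, ~6% of
gene-patient cells flag under the null, so every patient showing at least
one flagged gene is the statistically expected outcome at these
conditions.

The same analysis runs end-to-end from one call:

```r
library(adipolink)
report <- run_pipeline(run_config(simulation = sim_config(seed = 1),
                                  outdir = "results/run", seed = 1))
```

which writes every stage table as TSV plus a versioned `report.json`
holding all headline counts; identical seed and config reproduce it byte
for byte. Real datasets enter through `run_config(paths = list(...))`
with a TSV expression matrix, a sample table, a one-symbol-per-line panel
file, an edge list (TSV/SIF) and a GMT collection.

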