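---
title: "Linking a monogenic disease panel to case-control adipose transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking a monogenic disease panel to case-control adipose transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipolink)
```

## The scientific question

Familial partial lipodystrophy — selective loss of peripheral subcutaneous
adipose tissue with severe insulin resistance — is monogenic, while type 2
diabetes (T2D) in populations with a "thin fat" body composition is
polygenic but phenotypically similar. A natural systems-level question is
whether the *expression* of known lipodystrophy genes in the peripheral
subcutaneous adipose tissue of diabetics misbehaves in ways that connect
the two diseases. `adipolink` implements that analysis as a reusable,
fully testable pipeline over six stages:

1. **Trait comparisons** — Welch t-tests of intermediate phenotypes
   (HOMA-IR, HbA1c, lipids, adipokines, ...) between control (NGT) and
   case (T2D) groups, per sex stratum, either from raw vectors or from a
   published mean ± SD summary table.
2. **Differential expression** — non-specific filtering followed by an
   empirical-Bayes moderated t per gene, then intersection with the
   disease gene panel.
3. **Interactome overlap** — the disease panel's first-degree
   neighbourhood in a protein-interaction network, the fraction of DEGs
   falling inside it, reduction to the disease-DEG neighbourhood, and
   dual-centrality hub prioritization (top-k by degree ∪ top-k by
   bottleneck centrality).
4. **Over-representation analysis** — hypergeometric enrichment of the
   prioritized hubs against a gene-set collection, reporting size,
   expected overlap, enrichment ratio, p and BH-FDR.
5. **Co-expression modules** — a WGCNA-style analysis of the disease-panel
   submatrix run separately per group: soft-threshold adjacency, topological
   overlap, static tree cut, module eigengenes, eigengene–trait Pearson
   correlations.
6. **Individualization** — per-patient flagging of panel genes whose
   expression leaves a control-derived envelope, with population
   frequencies of flagged genes.

A synthetic-cohort generator (`simulate_dataset()`) emits datasets with
exactly the statistical structure these stages assume, plus a complete
truth record, so each stage is validated by parameter recovery rather than
by re-downloading the original microarray series.

## Models and statistics

### Moderated t (stage 2)

For gene $g$ with pooled two-group residual variance $s_g^2$ on
$d_g = n_1 + n_2 - 2$ degrees of freedom, the prior
$s_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ is fitted by closed-form moment
matching on $\log s_g^2$: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior df solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ (trigamma inversion by
Newton iteration, tolerance $10^{-8}$), falling back to $d_0 = \infty$
when the right-hand side is non-positive (all gene variances essentially
equal — no excess dispersion to shrink). Then
$s_{post}^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
$\tilde t_g = \Delta\bar x_g / (s_{post}\sqrt{1/n_1 + 1/n_2})$, with
p-values on $d_0 + d_g$ df. The test suite verifies this against the
reference empirical-Bayes implementation in `limma` to $10^{-10}$, and the
type-I error on null cohorts (2000 genes × 60 samples, 200 replicates
pooled) stays at $0.05 \pm 0.01$.

DEGs are declared at unadjusted $p < 0.05$ — deliberately, because the
interactome-overlap stage consumes a generous candidate list; BH-FDR
q-values are always carried alongside. The two-group contrast has no
covariates: the cohort design (1:1 sex ratio in both groups,
post-menopausal women) controls the main confounder by construction, and
sex-stratified modeling is out of scope.

### Bottleneck centrality (stage 3)

For every root $s$ a BFS shortest-path tree $T_s$ is grown over $s$'s
component. Tie-breaking is made fully deterministic: each node's parent is
its lexicographically smallest shortest-path predecessor. Node $v$ scores
one point from root $s$ iff its subtree in $T_s$ (counting $v$) contains
more than $|V(T_s)|/4$ nodes; consequently every root scores from its own
tree, and in a 2-node component both nodes score. $BN(v)$ sums over all
roots. These two conventions (lowest-ID parent, root self-scoring) are
design choices fixed for reproducibility — the metric's common
implementations leave them undocumented. The implementation is C++ (one
BFS per root); an independent pure-R oracle that walks parent chains
validates it exhaustively on all labeled 4-node graphs and on random
5–8-node and 40-node graphs.

Prioritization takes exactly `k` nodes per metric (ties broken by gene
symbol ascending, reproducibility over inclusiveness) and returns the
union, so the hub set has between `k` and `2k` genes.

### Over-representation (stage 4)

With reference universe size $N$, set size $K$ (after intersection with
the reference), input size $n$ (after dropping genes outside the
reference) and overlap $k$: expected overlap $nK/N$, enrichment ratio
$k/(nK/N)$, and $p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$,
one-sided because only over-representation is asked. When no explicit
universe is supplied the union of all set members is used — the reference
any annotation-driven web tool uses is unrecoverable after the fact, and
the union is the most defensible self-contained choice; the choice is
recorded in the run report. Sets smaller than 3 in the reference are
skipped to avoid degenerate expected counts. p-values match exact pmf
enumeration to $10^{-12}$.

### Co-expression modules (stage 5)

The analysis runs on the disease-panel submatrix only, per group — the
question is how the *panel* organizes in controls versus cases, not
transcriptome-wide module discovery. Unsigned adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with $\beta = 15$ (the value at
which the panel network approximates scale-free topology; the
`scale_free_fit()` diagnostic reports the log–log regression $R^2$),
topological overlap
$TOM_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i, k_j) + 1 - a_{ij})$, average
linkage on $1 - TOM$, and a **static** cut:

- Clusters at height `cut_height` with fewer than `min_module_size`
  members become grey; survivors are colored by descending size
  (turquoise, blue, ...).
- `cut_height = 0.998` by design: under a power adjacency a coherent block
  with within-correlation $r$ sits near $1 - r^\beta$ dissimilarity
  ($\approx 0.96$ at $r = 0.81$, $\beta = 15$) while uncorrelated gene
  pairs sit at $1 - TOM \approx 1 - 10^{-6}$. The cut therefore goes close
  to 1; $1 - \texttt{cut\_height}$ is the minimum detectable topological
  overlap, and 0.998 admits blocks with $r \gtrsim 0.66$ with three
  orders of magnitude of margin above the noise floor. The Dynamic Tree
  Cut algorithm is deliberately not reimplemented; the static cut is
  parameterized so that planted-block recovery does not depend on the
  variant.

Module eigengenes are the first principal component of the per-gene
standardized module submatrix, scaled to unit variance and sign-oriented
to correlate positively with the module's mean profile; grey receives an
eigengene too, because unassigned panel genes are still biologically
interesting against traits. Eigengene–trait associations use Pearson
correlation with pairwise-complete missing-trait handling and per-pair
$n - 2$ df in the Student-t p-value.

### Individualization (stage 6)

The method is described in the source literature both as a ±2·SD rule and
as a ±2-fold rule, so both are implemented: `sd` mode (default) flags a
case sample's gene when it leaves
$\mu_c \pm \mathrm{threshold}\cdot\sigma_c$ (control mean and sample SD);
`fold` mode uses a $\log_2(\mathrm{threshold})$ half-width on the log2
scale (the package's expression contract is always log2, which makes
"2-fold" exactly a ±1 shift). Degenerate control SDs are floored at
`min_control_sd` rather than flagging unconditionally, so constant probes
cannot flood the patient lists. Flag sets are nested: raising the
threshold never adds a flag.

A subtlety the tests respect: with an envelope *estimated* from $n_c = 30$
controls, the per-cell null flag rate is not the Gaussian
$2\Phi(-2) \approx 4.6\%$ but the exact
$2P(t_{29} > 2\sqrt{30/31}) \approx 5.9\%$, converging to the Gaussian
value as controls grow; and cells sharing a gene share $\hat\mu_c,
\hat\sigma_c$, which widens the variance of the observed rate. The
calibration tests use this exact finite-sample law.

## The synthetic cohort

`sim_config()` defaults are the study conditions and are not tuned per
test:

| parameter | default | meaning |
|---|---|---|
| `n_control`, `n_case` | 30 / 30 | biopsy counts, 1:1 sex ratio |
| `n_genes` | 5000 | genome-scale background, Normal(8, σ) log2 |
| `sigma_gene` | 0.5 | per-gene SD on log2 scale |
| `n_de`, `de_effect` | 100, 1.0 | planted DEGs, ±1.0 log2 in cases, half up/half down |
| `n_de_disease` (`de_disease_up`) | 16 (7) | panel members among the DEGs, 7 up / 9 down |
| `n_disease_genes` | 138 | disease panel size |
| `n_modules` × `module_size` | 2 × 30 | co-expression blocks inside the panel |
| `module_cor` | 0.9 | factor loading → within-block correlation ≈ 0.81 |
| `trait_coupling` | 0.6 | factor–trait correlation (Cell_size, LDL) |
| `network_attachment` | 3 | preferential-attachment edges per node |
| `n_outlier_patients`, `outlier_shift` | 25, 3 | cases with planted ±3σ panel outliers |

Block genes follow
$x_g = 8 + \sigma(\lambda F_b + \sqrt{1-\lambda^2}\,\varepsilon)$ for a
per-sample latent factor $F_b$; each coupled trait is
$0.6 F_b + \sqrt{1-0.36}\,\eta$. The interaction network grows by
preferential attachment with the panel genes injected first, so they are
high-degree-prone, as curated disease genes are in real interactomes.
Planted outliers *set* the target cell to
$\hat\mu_c + \mathrm{shift}\cdot\hat\sigma_c$ using the emitted control
samples' empirical moments, so a planted shift is exactly the deviation
the flagging stage measures; an additive-noise variant would leave ~16% of
3σ plants below a 2σ threshold by chance and make exact-recovery testing
ill-posed.

What the generator does **not** emulate: probe-level microarray noise,
batch effects, sex-stratified biology, heavy-tailed expression, correlated
trait panels, and literature-curation bias in the interactome. Passing
recovery tests therefore demonstrates that the statistics are implemented
correctly and calibrated under their own assumptions — not that the
original biological findings replicate.

## Numerical and reproducibility choices

- Single integer seed per simulation; all randomness flows from one
  generator, and identical config + seed reproduce every artifact and the
  JSON run report byte for byte.
- Gene identifiers match case-sensitively after whitespace stripping; no
  alias resolution (a data-curation concern outside the method).
- Expression is log2 by contract; `log2_transform` at ingest handles
  raw-scale files.
- hclust/cutree with average linkage is deterministic for fixed input
  order; module color ties break on the lexicographically first gene.
- Welch is used for trait comparisons (not pooled-variance t): the male
  published summary rows reproduce the printed p-values under Welch df at
  n = 15 per cell. Several female rows do not reproduce under either
  flavor with n = 15/15 — most plausibly unequal per-cell n in the source
  — and are excluded from worked-example checks; the discrepancy is
  visible in `analysis/02_trait_tests.R`'s output.
- The pipeline driver recomputes stages on every run rather than caching
  by config hash; runs are cheap and caching would add hidden state.

## Problem sizes used in validation

The validation suite uses a 2000-gene null cohort over 200 replicates for
type-I calibration, 100 seeded 300-gene cohorts for module recovery, a
1000-gene cohort for outlier recovery, exhaustive 4-node plus sampled
5–8- and 40-node graphs for centrality oracles, and the full 5000-gene
default cohort for the end-to-end run — sizes chosen to give tight Monte
Carlo error on each calibrated quantity while keeping a complete run in
minutes on a laptop.

## Known limitations

- The static tree cut cannot split nested or overlapping modules the way
  dynamic hybrid cutting can; module merging by eigengene similarity and
  consensus modules across groups are out of scope.
- The ORA reference-universe default (union of set members) makes
  absolute enrichment p-values depend on the supplied collection, as they
  do for any choice of universe.
- With a 138-gene panel and a ±2σ envelope, ~5.9% of cells flag under the
  null, so essentially every patient carries at least one flagged gene by
  chance; interpretation should lean on per-gene frequencies and planted
  or replicated signals, not on the bare patients-with-any count.
- Counts such as "number of DEGs" are dataset-specific; on synthetic
  cohorts they reflect the generator's conditions, not any real cohort.
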