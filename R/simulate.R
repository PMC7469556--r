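#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the cohort the pipeline was designed around: 30 control
#' (NGT) and 30 case (T2D) adipose biopsies with a 1:1 sex ratio, a
#' genome-scale log2 expression matrix, a 138-gene monogenic disease panel,
#' planted differential expression, planted co-expression blocks inside the
#' disease panel coupled to latent intermediate traits, a scale-free
#' interaction network in which the disease genes are early
#' (high-degree-prone) nodes, and per-patient outlier genes in 25 of the 30
#' cases.
#'
#' @param n_control,n_case group sizes (default 30/30).
#' @param n_genes total genes (default 5000).
#' @param n_de planted differentially expressed genes (default 100), half
#'   up / half down.
#' @param n_de_disease how many planted DE genes are disease-panel members
#'   (default 16), split `de_disease_up` up (default 7), rest down.
#' @param de_effect mean log2 case-control shift delta (default 1.0).
#' @param sigma_gene per-gene noise SD on log2 scale (default 0.5).
#' @param n_modules,module_size planted co-expression blocks within the
#'   disease panel (default 2 blocks of 30).
#' @param module_cor loading of each block gene on its latent factor
#'   (default 0.9, i.e. within-block pairwise correlation ~0.81).
#' @param trait_coupling correlation of each latent factor with its named
#'   trait (default 0.6).
#' @param coupled_traits trait names driven by the factors, recycled over
#'   modules (default Cell_size for block 1, LDL for block 2, echoing the
#'   traits the turquoise module tracks in diabetics).
#' @param n_disease_genes disease-panel size (default 138).
#' @param network_attachment edges added per node in preferential
#'   attachment (default 3).
#' @param n_decoy_sets random decoy gene sets alongside one set per planted
#'   block (default 20).
#' @param outlier_spec data.frame (`sample_id`, `gene`, `shift` in
#'   control-SD units) of planted per-patient deviations, or `NULL` to
#'   auto-generate: 25 distinct cases, 1-3 disease genes each, shifts of
#'   magnitude `outlier_shift` with random sign.
#' @param n_outlier_patients,outlier_shift used when auto-generating
#'   `outlier_spec` (defaults 25 and 3 control SDs).
#' @param seed single integer; every source of randomness flows from it.
#' @return a validated config (list, class `sim_config`).
#' @export
sim_config <- function(n_control = 30, n_case = 30, n_genes = 5000,
                       n_de = 100, n_de_disease = 16, de_disease_up = 7,
                       de_effect = 1.0, sigma_gene = 0.5,
                       n_modules = 2, module_size = 30, module_cor = 0.9,
                       trait_coupling = 0.6,
                       coupled_traits = c("Cell_size", "LDL"),
                       n_disease_genes = 138, network_attachment = 3,
                       n_decoy_sets = 20, outlier_spec = NULL,
                       n_outlier_patients = 25, outlier_shift = 3,
                       seed = 1L) {
  cfg <- list(n_control = n_control, n_case = n_case, n_genes = n_genes,
              n_de = n_de, n_de_disease = n_de_disease,
              de_disease_up = de_disease_up, de_effect = de_effect,
              sigma_gene = sigma_gene, n_modules = n_modules,
              module_size = module_size, module_cor = module_cor,
              trait_coupling = trait_coupling, coupled_traits = coupled_traits,
              n_disease_genes = n_disease_genes,
              network_attachment = network_attachment,
              n_decoy_sets = n_decoy_sets, outlier_spec = outlier_spec,
              n_outlier_patients = n_outlier_patients,
              outlier_shift = outlier_shift, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_control >= 2, n_case >= 2, n_genes >= 1, n_de >= 0,
              n_de <= n_genes, sigma_gene > 0, de_effect >= 0,
              n_modules >= 0, module_size >= 2,
              module_cor > 0, module_cor < 1,
              trait_coupling > 0, trait_coupling < 1,
              network_attachment >= 1, n_disease_genes >= 1,
              n_outlier_patients <= n_case)
    if (n_modules * module_size > n_disease_genes) {
      stop_fmt("planted blocks (%d x %d) exceed the disease panel (%d genes)",
               n_modules, module_size, n_disease_genes)
    }
    if (n_de_disease > n_de) stop_fmt("n_de_disease cannot exceed n_de")
    if (n_disease_genes > n_genes) stop_fmt("disease panel larger than n_genes")
    if (n_de - n_de_disease > n_genes - n_disease_genes) {
      stop_fmt("%d background DE genes requested but only %d genes outside the disease panel",
               n_de - n_de_disease, n_genes - n_disease_genes)
    }
  })
  structure(cfg, class = "sim_config")
}

# Intermediate-trait panel measured on the cohort; names follow the field's
# usual abbreviations.
trait_panel <- function() {
  c("Cell_size", "HOMA_IR", "HOMA_B", "HbA1c", "Triglycerides",
    "Cholesterol", "NEFA", "VLDL", "LDL", "HDL", "Leptin", "Adiponectin",
    "TNF_alpha", "hsCRP", "Serum_creatinine", "Insulin")
}

#' Generate a synthetic case-control cohort with a full truth record
#'
#' Background expression is Normal(8, `sigma_gene`) on the log2 scale.
#' Planted DE genes receive a +/- `de_effect` shift in cases. Block genes
#' follow `x = 8 + sigma_gene * (module_cor * F_b + sqrt(1 - module_cor^2) * eps)`
#' for a per-sample latent factor `F_b`; each coupled trait is
#' `trait_coupling * F_b + sqrt(1 - trait_coupling^2) * noise` (remaining
#' panel traits are pure noise). The interaction network grows by
#' preferential attachment with the disease genes as the earliest nodes.
#' Planted outliers overwrite the value of (gene, patient) cells with
#' `empirical control mean + shift * empirical control SD`, so a planted
#' shift is exactly the deviation the individualization stage measures (up
#' to later re-estimation on the same samples).
#'
#' @param config a [sim_config()].
#' @return list with elements `expression`, `samples`, `network`,
#'   `gene_sets`, `truth`. `truth` records planted DE effects, block
#'   membership, factor matrix, trait map, disease panel and outlier
#'   triples.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_s <- config$n_control + config$n_case
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  samples <- c(sprintf("CTRL%02d", seq_len(config$n_control)),
               sprintf("CASE%02d", seq_len(config$n_case)))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))

  disease_genes <- genes[seq_len(config$n_disease_genes)]

  # planted co-expression blocks live inside the disease panel
  module_genes <- list()
  pool <- disease_genes
  for (b in seq_len(config$n_modules)) {
    pick <- sample(pool, config$module_size)
    module_genes[[b]] <- sort_c(pick)
    pool <- setdiff(pool, pick)
  }
  names(module_genes) <- if (config$n_modules) paste0("block", seq_len(config$n_modules))

  # planted DE: disease-panel members (outside blocks) + background genes
  de_disease <- if (config$n_de_disease)
    sample(setdiff(pool, unlist(module_genes)), config$n_de_disease) else character()
  de_bg_pool <- setdiff(genes, c(disease_genes, unlist(module_genes)))
  de_bg <- if (config$n_de > config$n_de_disease)
    sample(de_bg_pool, config$n_de - config$n_de_disease) else character()
  n_bg_up <- ceiling(length(de_bg) / 2)  # half up, half down
  de_genes <- c(de_disease, de_bg)
  n_dis_up <- min(config$de_disease_up, length(de_disease))
  de_sign <- c(rep(c(1, -1), c(n_dis_up, length(de_disease) - n_dis_up)),
               rep(c(1, -1), c(n_bg_up, length(de_bg) - n_bg_up)))

  # expression: background noise, then factors, then DE shifts
  X <- matrix(rnorm(config$n_genes * n_s, mean = 8, sd = config$sigma_gene),
              nrow = config$n_genes, dimnames = list(genes, samples))
  factors <- matrix(rnorm(n_s * config$n_modules), nrow = n_s,
                    dimnames = list(samples, names(module_genes)))
  for (b in seq_along(module_genes)) {
    gs <- module_genes[[b]]
    eps <- matrix(rnorm(length(gs) * n_s), nrow = length(gs))
    X[gs, ] <- 8 + config$sigma_gene *
      (config$module_cor * matrix(factors[, b], nrow = length(gs),
                                  ncol = n_s, byrow = TRUE) +
         sqrt(1 - config$module_cor^2) * eps)
  }
  if (length(de_genes)) {
    X[de_genes, group == "case"] <- X[de_genes, group == "case"] +
      de_sign * config$de_effect
  }

  # traits: coupled ones track their block factor, the rest are noise
  traits <- matrix(rnorm(n_s * length(trait_panel())), nrow = n_s,
                   dimnames = list(samples, trait_panel()))
  trait_map <- character()
  if (config$n_modules) {
    trait_map <- rep_len(config$coupled_traits, config$n_modules)
    names(trait_map) <- names(module_genes)
    for (b in seq_len(config$n_modules)) {
      traits[, trait_map[b]] <- config$trait_coupling * factors[, b] +
        sqrt(1 - config$trait_coupling^2) * rnorm(n_s)
    }
  }

  smp <- sample_table(data.frame(
    sample_id = samples, group = group,
    sex = rep_len(c("M", "F"), n_s),
    traits, check.names = FALSE, stringsAsFactors = FALSE))

  # outliers: overwrite cells at control mean + shift * control SD
  outliers <- config$outlier_spec
  if (is.null(outliers)) {
    pats <- sample(samples[group == "case"], config$n_outlier_patients)
    outliers <- do.call(rbind, lapply(pats, function(p) {
      gs <- sample(disease_genes, sample(1:3, 1))
      data.frame(sample_id = p, gene = gs,
                 shift = config$outlier_shift * sample(c(-1, 1), length(gs),
                                                       replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(outliers)) {
    ctrl <- samples[group == "control"]
    mu_c <- rowMeans(X[outliers$gene, ctrl, drop = FALSE])
    sd_c <- apply(X[outliers$gene, ctrl, drop = FALSE], 1, sd)
    X[cbind(outliers$gene, outliers$sample_id)] <- mu_c + outliers$shift * sd_c
  }

  # scale-free network, disease genes first (high-degree-prone)
  node_order <- c(disease_genes, setdiff(genes, disease_genes))
  g <- igraph::sample_pa(config$n_genes, power = 1,
                         m = config$network_attachment, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_order)
  g <- igraph::simplify(g)

  # gene sets: one per planted block + random decoys
  sets <- module_genes
  if (config$n_decoy_sets) {
    decoys <- lapply(seq_len(config$n_decoy_sets), function(i)
      sort_c(sample(genes, config$module_size)))
    names(decoys) <- paste0("decoy", seq_len(config$n_decoy_sets))
    sets <- c(sets, decoys)
  }
  gsc <- gene_set_collection(sets,
                             descriptions = c(rep("planted", length(module_genes)),
                                              rep("decoy", length(sets) - length(module_genes))))

  truth <- list(
    de_genes = data.frame(gene = de_genes, effect = de_sign * config$de_effect,
                          is_disease = de_genes %in% disease_genes,
                          stringsAsFactors = FALSE),
    modules = module_genes,
    factors = factors,
    trait_map = trait_map,
    disease_genes = disease_genes,
    outliers = outliers)

  list(expression = expression_matrix(X), samples = smp, network = g,
       gene_sets = gsc, truth = truth)
}

#' Write all artifacts of a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `samples.tsv`, `network.tsv`, `gene_sets.gmt`,
#' `disease_genes.txt` and `truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_network(sim$network, file.path(dir, "network.tsv"))
  write_gene_sets(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_gene_list(sim$truth$disease_genes, file.path(dir, "disease_genes.txt"))
  truth <- sim$truth
  truth$factors <- as.data.frame(truth$factors)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
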