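#' Assemble a pipeline run configuration
#'
#' Exactly one of `paths` (named list: `expression`, `samples`,
#' `disease_genes`, `network`, optional `gene_sets`) or `simulation` (a
#' [sim_config()]) must be given.
#'
#' @param paths input file paths for a real dataset.
#' @param simulation a [sim_config()] for a synthetic run.
#' @param outdir output directory for stage TSVs and the run report.
#' @param stages character subset of
#'   `c("traits", "dge", "network", "ora", "wgcna", "individualize")`;
#'   prerequisites of a requested stage are computed but only requested
#'   stages write outputs and appear in the report.
#' @param diffexpr,prioritize_k,coexpression,individualization stage
#'   parameter blocks ([diffexpr_params()], top-k per centrality metric,
#'   [coexpression_params()], [individualization_params()]).
#' @param ora_reference optional explicit reference universe for [ora()].
#' @param seed integer seed (used by the simulation block).
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = NULL, simulation = NULL, outdir = tempfile("adipolink_"),
                       stages = c("traits", "dge", "network", "ora", "wgcna",
                                  "individualize"),
                       diffexpr = diffexpr_params(), prioritize_k = 100,
                       coexpression = coexpression_params(),
                       individualization = individualization_params(),
                       ora_reference = NULL, seed = 1L) {
  if (is.null(paths) == is.null(simulation)) {
    stop_fmt("exactly one of 'paths' or 'simulation' must be supplied")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(paths = paths, simulation = simulation, outdir = outdir,
                 stages = stages, diffexpr = diffexpr,
                 prioritize_k = prioritize_k, coexpression = coexpression,
                 individualization = individualization,
                 ora_reference = ora_reference, seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    return(simulate_dataset(sim))
  }
  p <- config$paths
  list(expression = read_expression_matrix(p$expression),
       samples = read_sample_table(p$samples),
       network = read_network(p$network),
       gene_sets = if (!is.null(p$gene_sets)) read_gene_sets(p$gene_sets),
       truth = NULL,
       disease_genes = read_gene_list(p$disease_genes))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order and as requested: trait group comparisons,
#' filtering + moderated-t differential expression with disease-panel
#' intersection, disease-interactome construction with DEG overlap,
#' reduction and dual-centrality prioritization, over-representation
#' analysis of the prioritized hubs, per-group co-expression modules with
#' module-trait correlation, and per-patient deviation flagging. Stage
#' tables land in `config$outdir` as TSV; a versioned JSON run report
#' (`report.json`) carries every headline count. A stage error writes a
#' partial report before aborting.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = "1.0", seed = config$seed,
                 stages = config$stages,
                 params = list(
                   alpha = config$diffexpr$alpha,
                   use_moderation = config$diffexpr$use_moderation,
                   prioritize_k = config$prioritize_k,
                   beta = config$coexpression$beta,
                   cut_height = config$coexpression$cut_height,
                   min_module_size = config$coexpression$min_module_size,
                   individualize_mode = config$individualization$mode,
                   individualize_threshold = config$individualization$threshold))
  finish <- function(report, error = NULL) {
    if (!is.null(error)) report$error <- error
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                             pretty = TRUE, null = "null")
    writeLines(json, file.path(config$outdir, "report.json"))
    report
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      finish(report, error = list(stage = name, message = conditionMessage(e)))
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  want <- function(s) s %in% config$stages

  inputs <- run_stage("input", function() load_inputs(config))
  disease_genes <- inputs$disease_genes %||% inputs$truth$disease_genes
  report$n_samples <- nrow(inputs$samples)
  report$n_genes <- nrow(inputs$expression)
  report$n_disease_genes <- length(disease_genes)

  if (want("traits")) {
    tt <- run_stage("traits", function() trait_table(inputs$samples))
    write_tsv(tt, file.path(config$outdir, "trait_table.tsv"))
    report$traits <- list(n_traits = nrow(tt),
                          n_significant = sum(tt$p < 0.05, na.rm = TRUE))
  }

  need_dge <- any(vapply(c("dge", "network", "ora"), want, logical(1)))
  if (need_dge) {
    de <- run_stage("dge", function() {
      x <- nonspecific_filter(inputs$expression, config$diffexpr)
      moderated_t(x, inputs$samples, config$diffexpr)
    })
    degs <- select_degs(de, config$diffexpr$alpha)
    lipo <- intersect_disease_genes(degs, disease_genes)
    if (want("dge")) {
      write_tsv(de, file.path(config$outdir, "de_results.tsv"))
      write_tsv(degs, file.path(config$outdir, "degs.tsv"))
      report$dge <- list(n_genes_tested = nrow(de), n_degs = nrow(degs),
                         d0 = attr(de, "d0"), s02 = attr(de, "s02"),
                         disease_degs_up = as.list(lipo$up),
                         disease_degs_down = as.list(lipo$down),
                         n_disease_degs = unname(lipo$counts[["total"]]))
    }
  }

  need_net <- want("network") || want("ora")
  if (need_net) {
    netres <- run_stage("network", function() {
      subnet <- disease_neighborhood(inputs$network, disease_genes)
      ov <- overlap_stats(degs, subnet)
      seeds <- intersect(c(lipo$up, lipo$down), igraph::V(subnet)$name)
      if (!length(seeds)) {
        log_note("no disease-gene DEGs in the interactome; reducing on all overlap genes")
        seeds <- ov$overlap_genes
      }
      reduced <- reduce_to_overlap_neighborhood(subnet, seeds)
      prio <- prioritize_union(reduced, k = config$prioritize_k)
      list(subnet = subnet, ov = ov, reduced = reduced, prio = prio)
    })
    if (want("network")) {
      write_network(netres$subnet, file.path(config$outdir, "disease_subnetwork.tsv"))
      write_tsv(netres$prio$centrality, file.path(config$outdir, "centrality.tsv"))
      report$network <- list(
        interactome_nodes = igraph::vcount(netres$subnet),
        interactome_edges = igraph::ecount(netres$subnet),
        seed_attrition = attr(netres$subnet, "seed_attrition"),
        deg_overlap = netres$ov$n_overlap,
        deg_overlap_pct = netres$ov$pct_of_degs,
        reduced_nodes = igraph::vcount(netres$reduced),
        prioritized_nodes = length(netres$prio$nodes))
    }
  }

  if (want("ora") && !is.null(inputs$gene_sets)) {
    enr <- run_stage("ora", function()
      ora(netres$prio$nodes, inputs$gene_sets, reference = config$ora_reference))
    write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    report$ora <- list(n_sets_tested = nrow(enr),
                       n_input = attr(enr, "n_input"),
                       top = head(enr[, c("name", "size", "overlap", "expect",
                                          "ratio", "p", "fdr")], 10))
  }

  if (want("wgcna")) {
    wg <- run_stage("wgcna", function() {
      lapply(setNames(c("control", "case"), c("control", "case")), function(grp)
        coexpression_group(inputs$expression, inputs$samples, disease_genes,
                           grp, config$coexpression))
    })
    for (grp in names(wg)) {
      write_tsv(data.frame(gene = names(wg[[grp]]$assignment),
                           module = unname(wg[[grp]]$assignment),
                           group = grp),
                file.path(config$outdir, paste0("modules_", grp, ".tsv")))
      write_tsv(wg[[grp]]$module_trait,
                file.path(config$outdir, paste0("module_trait_", grp, ".tsv")))
    }
    report$wgcna <- lapply(wg, function(res) {
      sizes <- table(res$assignment)
      mt <- res$module_trait
      list(modules = as.list(setNames(as.integer(sizes), names(sizes))),
           n_significant_module_trait = sum(mt$p < 0.05, na.rm = TRUE),
           significant = mt[!is.na(mt$p) & mt$p < 0.05,
                            c("module", "trait", "r", "p")])
    })
  }

  if (want("individualize")) {
    ind <- run_stage("individualize", function() {
      env <- control_envelope(inputs$expression, inputs$samples, disease_genes,
                              config$individualization$min_control_sd)
      flags <- flag_patient_genes(inputs$expression, inputs$samples, env,
                                  config$individualization)
      list(flags = flags, freq = frequency_summary(flags))
    })
    write_tsv(ind$flags$flags, file.path(config$outdir, "patient_flags.tsv"))
    write_tsv(ind$freq$frequency, file.path(config$outdir, "gene_frequencies.tsv"))
    report$individualize <- list(
      patients_with_any = ind$freq$patients_with_any,
      n_cases = sum(inputs$samples$group == "case"),
      n_flagged_genes = nrow(ind$freq$frequency),
      top_genes = head(ind$freq$frequency, 10))
  }

  invisible(finish(report))
}
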