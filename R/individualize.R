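#' Parameters for per-patient deviation flagging
#'
#' Two envelope modes exist because the method is described both as a
#' +/- 2-SD rule and as a +/- 2-fold rule: `sd` mode flags values more than
#' `threshold` control SDs from the control mean; `fold` mode flags log2
#' differences beyond `log2(threshold)` (i.e. a 2-fold change at the
#' default threshold). `sd` is the default.
#'
#' @param mode `"sd"` or `"fold"`.
#' @param threshold envelope width: SD multiples in `sd` mode, fold change
#'   in `fold` mode (default 2 for both readings).
#' @param min_control_sd floor for a degenerate (constant-gene) control SD
#'   in `sd` mode (default 1e-6), so constant probes do not flag
#'   spuriously.
#' @return list of class `individualization_params`.
#' @export
individualization_params <- function(mode = c("sd", "fold"), threshold = 2,
                                     min_control_sd = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, min_control_sd > 0)
  structure(list(mode = mode, threshold = threshold,
                 min_control_sd = min_control_sd),
            class = "individualization_params")
}

#' Control-group expression envelope for a gene panel
#'
#' Per-gene mean and sample SD (n - 1 denominator) over the control
#' samples, restricted to the supplied disease genes present in the matrix
#' (absent ones are logged).
#'
#' @param x expression matrix.
#' @param samples sample table (>= 2 controls required).
#' @param genes disease gene panel.
#' @param min_control_sd SD floor for constant genes (flagged with a
#'   warning).
#' @return data.frame `gene`, `mean`, `sd`.
#' @export
control_envelope <- function(x, samples, genes, min_control_sd = 1e-6) {
  validate_expression_matrix(x)
  samples <- sample_table(samples)
  ctrl <- samples$sample_id[samples$group == "control"]
  if (length(ctrl) < 2) stop_fmt("need >= 2 control samples, have %d", length(ctrl))
  genes <- unique(trimws(genes))
  present <- intersect(genes, rownames(x))
  if (length(present) < length(genes)) {
    log_note("%d panel gene(s) absent from the expression matrix",
             length(genes) - length(present))
  }
  if (!length(present)) stop_fmt("no panel genes present in the matrix")
  sub <- x[present, ctrl, drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds < min_control_sd)) {
    warn_fmt("%d gene(s) with control SD below %g floored", sum(sds < min_control_sd),
             min_control_sd)
    sds <- pmax(sds, min_control_sd)
  }
  data.frame(gene = present, mean = rowMeans(sub), sd = sds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag per-patient deviating genes
#'
#' For each case sample, genes whose expression leaves the control
#' envelope: in `sd` mode, `x > mean + threshold*sd` (up) or
#' `x < mean - threshold*sd` (down); in `fold` mode the same with
#' `log2(threshold)` as the half-width (expression is log2 by contract).
#' Per-patient gene lists are alphabetical; a gene is never in both lists
#' for one patient.
#'
#' @param x expression matrix.
#' @param samples sample table.
#' @param envelope [control_envelope()] output.
#' @param params [individualization_params()].
#' @return list of class `patient_flags`: `flags` (data.frame
#'   `sample_id`, `gene`, `direction`, `deviation`), `per_patient` (list
#'   sample -> list(up, down)), `params`.
#' @export
flag_patient_genes <- function(x, samples, envelope,
                               params = individualization_params()) {
  validate_expression_matrix(x)
  samples <- sample_table(samples)
  cases <- samples$sample_id[samples$group == "case"]
  missing <- setdiff(cases, colnames(x))
  if (length(missing)) {
    stop_fmt("case sample(s) missing from expression matrix: %s",
             paste(missing, collapse = ", "))
  }
  sub <- x[envelope$gene, cases, drop = FALSE]
  dev <- sub - envelope$mean
  half <- switch(params$mode,
                 sd = params$threshold * envelope$sd,
                 fold = rep(log2(params$threshold), nrow(envelope)))
  up <- dev > half
  down <- dev < -half
  hit <- which(up | down, arr.ind = TRUE)
  flags <- data.frame(sample_id = cases[hit[, 2L]],
                      gene = envelope$gene[hit[, 1L]],
                      direction = ifelse(up[hit], "up", "down"),
                      deviation = dev[hit],
                      stringsAsFactors = FALSE)
  flags <- flags[order(flags$sample_id, flags$gene), , drop = FALSE]
  rownames(flags) <- NULL
  per_patient <- lapply(setNames(cases, cases), function(p) {
    f <- flags[flags$sample_id == p, ]
    list(up = sort_c(f$gene[f$direction == "up"]),
         down = sort_c(f$gene[f$direction == "down"]))
  })
  structure(list(flags = flags, per_patient = per_patient, params = params),
            class = "patient_flags")
}

#' Population frequency of flagged genes
#'
#' @param flags [flag_patient_genes()] output.
#' @return list `frequency` (data.frame `gene`, `n_patients`, up/down
#'   pooled, sorted by descending count then symbol) and
#'   `patients_with_any` (cases with >= 1 flagged gene).
#' @export
frequency_summary <- function(flags) {
  f <- flags$flags
  if (!nrow(f)) {
    return(list(frequency = data.frame(gene = character(),
                                       n_patients = integer(),
                                       stringsAsFactors = FALSE),
                patients_with_any = 0L))
  }
  tab <- table(unique(f[, c("gene", "sample_id")])$gene)
  freq <- data.frame(gene = names(tab), n_patients = as.integer(tab),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$n_patients, freq$gene), , drop = FALSE]
  rownames(freq) <- NULL
  list(frequency = freq,
       patients_with_any = length(unique(f$sample_id)))
}
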