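#' Construct and validate a log2 expression matrix
#'
#' The pipeline's core container is a plain numeric matrix of log2
#' intensities with genes in rows and samples in columns. By contract every
#' value entering downstream stages is on the log2 scale; raw-scale inputs
#' can be transformed at ingest via `log2_transform` in
#' [read_expression_matrix()].
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   existing dimnames.
#' @return the validated matrix (class `matrix`, rownames = genes,
#'   colnames = samples).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fmt("expression values must be a numeric matrix")
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

validate_expression_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_fmt("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(x) < 1L) stop_fmt("expression matrix needs at least one gene")
  if (ncol(x) < 2L) stop_fmt("expression matrix needs at least two samples")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    stop_fmt("duplicate gene identifier(s): %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stop_fmt("duplicate sample identifier(s): %s", paste(dup_s, collapse = ", "))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_fmt("non-finite expression value at gene '%s', sample '%s'",
             rownames(x)[bad[1L]], colnames(x)[bad[2L]])
  }
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Row and column order are preserved.
#'
#' @param path TSV file path.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` at ingest (for
#'   raw-intensity inputs); the in-memory contract is always log2 scale.
#' @return validated expression matrix.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_fmt("expression TSV '%s' needs a gene column and >= 2 samples", path)
  genes <- trimws(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop_fmt("duplicate gene identifier(s) in '%s': %s", path,
             paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_fmt("non-numeric expression value at row %d (gene '%s'), column '%s' in '%s'",
               bad[1L, 1L], genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], path)
    }
    stop_fmt("missing expression values in '%s'", path)
  }
  dimnames(num) <- list(genes, trimws(colnames(vals)))
  if (log2_transform) num <- log2(num + 1)
  expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene`, then one
#' column per sample.
#'
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
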