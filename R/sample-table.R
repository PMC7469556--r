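#' Construct and validate a sample annotation table
#'
#' A data.frame with one row per sample: `sample_id`, `group`
#' (`"control"`/`"case"`; the cohort labels NGT/T2D map onto these), `sex`
#' (`"M"`/`"F"`, optional), and any number of numeric trait columns
#' (intermediate phenotypes such as HOMA-IR, HbA1c, leptin ...). Missing
#' trait values are allowed (`NA`); present values must be finite.
#'
#' @param df data.frame with at least `sample_id` and `group` columns.
#' @return validated data.frame.
#' @export
sample_table <- function(df) {
  if (!is.data.frame(df)) stop_fmt("sample table must be a data.frame")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop_fmt("sample table needs 'sample_id' and 'group' columns")
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  df$group <- as.character(df$group)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop_fmt("duplicate sample id(s): %s", paste(dup, collapse = ", "))
  bad_grp <- setdiff(unique(df$group), c("control", "case"))
  if (length(bad_grp)) {
    stop_fmt("group labels must be 'control' or 'case'; found: %s",
             paste(bad_grp, collapse = ", "))
  }
  if ("sex" %in% names(df)) {
    bad_sex <- setdiff(unique(stats::na.omit(df$sex)), c("M", "F"))
    if (length(bad_sex)) stop_fmt("sex labels must be 'M' or 'F'")
  }
  for (tr in trait_names(df)) {
    v <- df[[tr]]
    if (!is.numeric(v)) stop_fmt("trait column '%s' must be numeric", tr)
    if (any(!is.finite(v) & !is.na(v))) stop_fmt("trait '%s' has non-finite values", tr)
  }
  rownames(df) <- NULL
  df
}

#' Names of the numeric trait columns of a sample table
#' @param samples sample table.
#' @return character vector of trait column names.
#' @export
trait_names <- function(samples) {
  setdiff(names(samples), c("sample_id", "group", "sex"))
}

#' Read / write a sample table (TSV)
#' @param path TSV with `sample_id`, `group`, optional `sex`, trait columns.
#' @return validated sample table.
#' @export
read_sample_table <- function(path) {
  sample_table(read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param samples sample table to write.
#' @export
write_sample_table <- function(samples, path) {
  write.table(sample_table(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a disease gene list (one symbol per line)
#'
#' Blank lines and leading/trailing whitespace are dropped; duplicates are
#' collapsed with a note. Matching downstream is case-sensitive.
#'
#' @param path text file, one gene symbol per line.
#' @return character vector of unique symbols, file order preserved.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  ndup <- sum(duplicated(x))
  if (ndup) log_note("dropped %d duplicate gene symbol(s) from '%s'", ndup, path)
  unique(x)
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(trimws(genes)), path)
  invisible(path)
}
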