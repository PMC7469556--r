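#' Gene set collections (GMT)
#'
#' A gene set collection is a named list of character vectors (member
#' symbols, deduplicated, non-empty) with a parallel `descriptions`
#' attribute and an optional explicit `reference` universe attribute used
#' by [ora()].
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @param reference optional explicit reference gene universe.
#' @return validated collection (named list with attributes).
#' @export
gene_set_collection <- function(sets, descriptions = NULL, reference = NULL) {
  if (is.null(names(sets)) && length(sets)) stop_fmt("gene sets must be named")
  sets <- lapply(sets, function(m) unique(trimws(as.character(m))))
  if (any(lengths(sets) == 0L)) stop_fmt("gene set member lists must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    stop_fmt("need one description per set")
  }
  structure(sets,
            descriptions = setNames(as.character(descriptions), names(sets)),
            reference = if (!is.null(reference)) unique(trimws(reference)),
            class = c("gene_set_collection", "list"))
}

#' Read gene sets in GMT format
#'
#' GMT dialect: `name TAB description TAB member1 TAB member2 ...`, one set
#' per line. Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return gene set collection; empty file gives an empty collection.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_fmt("GMT line %d in '%s' has fewer than 3 fields", short[1L], path)
  }
  nm <- vapply(fields, function(f) trimws(f[1L]), character(1))
  desc <- vapply(fields, function(f) trimws(f[2L]), character(1))
  members <- lapply(fields, function(f) {
    m <- trimws(f[-(1:2)])
    unique(m[nzchar(m)])
  })
  gene_set_collection(setNames(members, nm), descriptions = desc)
}

#' Write a gene set collection in GMT format
#' @param sets gene set collection.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
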