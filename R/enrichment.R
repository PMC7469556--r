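#' Benjamini-Hochberg FDR q-values
#'
#' Step-up BH adjustment with enforced monotonicity; input order preserved.
#' Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p) | p < 0 | p > 1)) stop_fmt("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, tests whether the input list is enriched relative to
#' a reference universe. With `N = |reference|`, `K` = set members in the
#' reference, `n` = input genes in the reference and `k` = overlap, the row
#' reports `expect = n*K/N`, `ratio = k/expect` and the one-sided
#' over-representation p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, plus BH-FDR across all tested sets.
#'
#' Input genes outside the reference are dropped (count logged). Sets with
#' fewer than `min_set_size` members after intersection with the reference
#' are skipped (logged) to avoid degenerate expected counts.
#'
#' @param input_genes character vector of query symbols.
#' @param sets a [gene_set_collection()].
#' @param reference explicit gene universe; defaults to the collection's
#'   `reference` attribute, else the union of all set members.
#' @param min_set_size smallest reference-intersected set tested (default 3).
#' @return data.frame: `name`, `description`, `size` (K), `overlap` (k),
#'   `expect`, `ratio`, `p`, `fdr`; rows sorted by p then name. Attribute
#'   `n_input` records n.
#' @export
ora <- function(input_genes, sets, reference = NULL, min_set_size = 3) {
  reference <- reference %||% attr(sets, "reference") %||%
    unique(unlist(sets, use.names = FALSE))
  reference <- unique(trimws(reference))
  if (!length(reference)) stop_fmt("reference universe is empty")
  input <- unique(trimws(input_genes))
  dropped <- setdiff(input, reference)
  if (length(dropped)) {
    log_note("dropped %d input gene(s) outside the reference universe",
             length(dropped))
  }
  input <- intersect(input, reference)
  if (!length(input)) stop_fmt("no input genes in the reference universe")
  N <- length(reference)
  n <- length(input)
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  rows <- list()
  skipped <- 0L
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], reference)
    K <- length(members)
    if (K < min_set_size) { skipped <- skipped + 1L; next }
    k <- length(intersect(input, members))
    expect <- n * K / N
    # P(X >= k); phyper is exact for the hypergeometric tail
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, description = desc[[nm]], size = K, overlap = k,
      expect = expect, ratio = k / expect, p = min(p, 1),
      stringsAsFactors = FALSE)
  }
  if (skipped) log_note("skipped %d set(s) smaller than %d in the reference",
                        skipped, min_set_size)
  if (!length(rows)) {
    out <- data.frame(name = character(), description = character(),
                      size = integer(), overlap = integer(),
                      expect = numeric(), ratio = numeric(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_input") <- n
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, out$name), ]
  rownames(out) <- NULL
  attr(out, "n_input") <- n
  out
}
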