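#' Parameters for weighted co-expression analysis
#'
#' @param beta soft-threshold power applied to absolute Pearson
#'   correlations (default 15, chosen for scale-free topology of the gene
#'   network).
#' @param cut_height static dendrogram cut on the 1 - TOM dissimilarity
#'   (default 0.998). Under an unsigned power adjacency the topological
#'   overlap of a coherent block with within-correlation `r` sits near
#'   `r^beta` while uncorrelated gene pairs sit orders of magnitude lower
#'   (~1e-6 at `beta = 15`), so the cut is placed close to 1: `1 - cut`
#'   bounds the weakest detectable block, and 0.998 admits blocks with
#'   `r >~ 0.66` at `beta = 15` with ample margin above the noise floor.
#' @param min_module_size clusters smaller than this become grey
#'   (default 10).
#' @return list of class `coexpression_params`.
#' @export
coexpression_params <- function(beta = 15, cut_height = 0.998,
                                min_module_size = 10) {
  stopifnot(beta >= 1, cut_height > 0, cut_height <= 1, min_module_size >= 2)
  structure(list(beta = beta, cut_height = cut_height,
                 min_module_size = min_module_size),
            class = "coexpression_params")
}

# WGCNA's conventional module color sequence, by descending module size.
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base)) + length(base)))
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^beta` with zero
#' diagonal. Genes with zero variance across samples are excluded with a
#' warning (their correlation is undefined).
#'
#' @param x expression matrix (genes x samples, >= 3 samples).
#' @param beta soft-threshold power.
#' @return symmetric adjacency matrix with entries in \[0, 1\].
#' @export
soft_adjacency <- function(x, beta = 15) {
  validate_expression_matrix(x)
  if (ncol(x) < 3) stop_fmt("soft adjacency needs >= 3 samples")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    warn_fmt("excluding %d zero-variance gene(s) from the network", sum(v == 0))
    x <- x[v > 0, , drop = FALSE]
  }
  a <- abs(cor(t(x)))^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Connectivities `k_i = sum_j a_ij` are binned into `n_bins` equal-width
#' bins; the log10 frequency of each occupied bin is regressed on the
#' log10 of its mean connectivity. Returns the regression R-squared and
#' slope (a good scale-free fit has high R-squared and negative slope).
#'
#' @param adjacency symmetric adjacency matrix (>= 10 genes).
#' @param n_bins histogram bins (default 10).
#' @return list `r_squared`, `slope`; both `NA` when all connectivities
#'   are equal (fit undefined).
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  if (nrow(adjacency) < 10) stop_fmt("scale-free fit needs >= 10 genes")
  k <- rowSums(adjacency)
  if (diff(range(k)) == 0) return(list(r_squared = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = n_bins)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu * a_uj` and unit diagonal: the similarity of
#' two genes' weighted neighborhoods, not just their direct connection.
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @return symmetric TOM matrix, entries in \[0, 1\], diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  k <- rowSums(a)
  l <- a %*% a                      # includes no i/j terms since diag(a) = 0
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the 1 - TOM dissimilarity,
#' flat clusters at `cut_height`; clusters below `min_module_size` are
#' pooled into grey. Surviving modules are colored by descending size
#' (largest = turquoise, then blue, ...), ties broken by first gene symbol.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param params [coexpression_params()].
#' @return named character vector gene -> color label (class
#'   `module_assignment` via its names), every input gene labeled.
#' @export
detect_modules <- function(tom, params = coexpression_params()) {
  genes <- rownames(tom)
  if (length(genes) < 2) return(setNames(rep("grey", length(genes)), genes))
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  assignment <- setNames(rep("grey", length(genes)), genes)
  if (length(keep)) {
    first_gene <- vapply(keep, function(id) sort_c(genes[cl == id])[1L],
                         character(1))
    keep <- keep[order(-sizes[keep], first_gene)]
    cols <- module_colors(length(keep))
    for (i in seq_along(keep)) {
      assignment[cl == as.integer(keep[i])] <- cols[i]
    }
  }
  assignment
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized (per-gene mean 0, SD 1) expression submatrix, scaled to
#' unit variance over samples and sign-oriented to correlate positively
#' with the module's mean standardized profile. Grey receives an eigengene
#' too, since unassigned disease genes are still correlated with traits
#' downstream.
#'
#' @param x expression matrix (genes x samples).
#' @param assignment named vector from [detect_modules()].
#' @return matrix samples x modules (columns `MEturquoise`, ...).
#' @export
module_eigengenes <- function(x, assignment) {
  validate_expression_matrix(x)
  miss <- setdiff(names(assignment), rownames(x))
  if (length(miss)) stop_fmt("assigned gene(s) missing from matrix: %s",
                             paste(head(miss, 5), collapse = ", "))
  mods <- unique(assignment)
  mes <- sapply(mods, function(col) {
    gs <- names(assignment)[assignment == col]
    sub <- x[gs, , drop = FALSE]
    std <- t(scale(t(sub)))          # per-gene standardization
    std[!is.finite(std)] <- 0        # constant genes contribute nothing
    if (nrow(std) == 1L) {
      warn_fmt("module '%s' has a single gene; eigengene = that gene", col)
      me <- std[1L, ]
    } else {
      me <- prcomp(t(std), center = FALSE, scale. = FALSE)$x[, 1L]
    }
    if (sd(me) > 0) me <- me / sd(me)
    mean_profile <- colMeans(std)
    ornt <- cor(me, mean_profile)
    if (!is.na(ornt) && ornt < 0) me <- -me
    me
  })
  colnames(mes) <- paste0("ME", mods)
  rownames(mes) <- colnames(x)
  mes
}

#' Module-trait relationships
#'
#' Pearson correlation of each module eigengene with each numeric trait,
#' pairwise-complete over missing values, with the two-sided Student-t
#' p-value on `n - 2` degrees of freedom (`n` = complete pairs for that
#' cell). Constant traits give `NA` (undefined marker).
#'
#' @param mes eigengene matrix from [module_eigengenes()].
#' @param samples sample table with trait columns, matched by `sample_id`.
#' @return data.frame: `module`, `trait`, `r`, `n`, `p`.
#' @export
module_trait_relationships <- function(mes, samples) {
  samples <- sample_table(samples)
  idx <- match(rownames(mes), samples$sample_id)
  if (anyNA(idx)) stop_fmt("eigengene sample(s) missing from sample table")
  samples <- samples[idx, , drop = FALSE]
  rows <- list()
  for (mod in colnames(mes)) {
    for (tr in trait_names(samples)) {
      v <- samples[[tr]]
      ok <- !is.na(v)
      n <- sum(ok)
      r <- p <- NA_real_
      if (n >= 4 && sd(v[ok]) > 0 && sd(mes[ok, mod]) > 0) {
        r <- cor(mes[ok, mod], v[ok])
        if (abs(r) >= 1) {
          p <- 0
        } else {
          tstat <- r * sqrt((n - 2) / (1 - r^2))
          p <- 2 * pt(-abs(tstat), n - 2)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = sub("^ME", "", mod), trait = tr, r = r, n = n, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group co-expression analysis of a disease-gene submatrix
#'
#' Runs the full module pipeline (adjacency, TOM, static-cut modules,
#' eigengenes, module-trait correlations) on the disease-panel submatrix
#' of one sample group, mirroring the design in which control and case
#' networks are built separately and compared.
#'
#' @param x full expression matrix.
#' @param samples sample table.
#' @param disease_genes panel symbols (absent genes logged and skipped).
#' @param group `"control"` or `"case"`.
#' @param params [coexpression_params()].
#' @return list `assignment`, `eigengenes`, `module_trait`,
#'   `scale_free` (fit of the group network).
#' @export
coexpression_group <- function(x, samples, disease_genes, group,
                               params = coexpression_params()) {
  samples <- sample_table(samples)
  keep <- samples[samples$group == group, , drop = FALSE]
  if (!nrow(keep)) stop_fmt("no samples in group '%s'", group)
  genes <- intersect(disease_genes, rownames(x))
  if (length(genes) < length(disease_genes)) {
    log_note("%d of %d disease gene(s) absent from the expression matrix",
             length(disease_genes) - length(genes), length(disease_genes))
  }
  if (length(genes) < params$min_module_size) {
    stop_fmt("only %d disease genes present; need >= %d", length(genes),
             params$min_module_size)
  }
  sub <- x[genes, keep$sample_id, drop = FALSE]
  adj <- soft_adjacency(sub, beta = params$beta)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, params)
  mes <- module_eigengenes(sub[rownames(tom), , drop = FALSE], assignment)
  mt <- module_trait_relationships(mes, keep)
  list(assignment = assignment, eigengenes = mes, module_trait = mt,
       scale_free = scale_free_fit(adj))
}
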