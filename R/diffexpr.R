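#' Parameters for filtering and differential expression
#'
#' @param filter_min_intensity,filter_min_fraction keep genes whose log2
#'   intensity exceeds `filter_min_intensity` in at least
#'   `filter_min_fraction` of samples (0/0 disables).
#' @param filter_min_iqr keep genes with across-sample IQR at least this
#'   (0 disables).
#' @param alpha unadjusted p threshold declaring a DEG (default 0.05).
#' @param use_moderation empirical-Bayes variance moderation (default
#'   `TRUE`); with `FALSE` the statistic reduces to the ordinary
#'   equal-variance two-sample t.
#' @return list of class `diffexpr_params`.
#' @export
diffexpr_params <- function(filter_min_intensity = 0, filter_min_fraction = 0,
                            filter_min_iqr = 0, alpha = 0.05,
                            use_moderation = TRUE) {
  stopifnot(alpha > 0, alpha < 1, filter_min_fraction >= 0,
            filter_min_fraction <= 1, filter_min_iqr >= 0)
  structure(list(filter_min_intensity = filter_min_intensity,
                 filter_min_fraction = filter_min_fraction,
                 filter_min_iqr = filter_min_iqr, alpha = alpha,
                 use_moderation = use_moderation),
            class = "diffexpr_params")
}

#' Non-specific filtering of an expression matrix
#'
#' Removes genes that fail either criterion: intensity above
#' `filter_min_intensity` in at least `filter_min_fraction` of samples, and
#' IQR of at least `filter_min_iqr`. Filtering is label-blind (it never
#' looks at group membership), so it does not bias the downstream test.
#'
#' @param x expression matrix.
#' @param params [diffexpr_params()].
#' @return filtered expression matrix; hard error if nothing survives.
#' @export
nonspecific_filter <- function(x, params = diffexpr_params()) {
  validate_expression_matrix(x)
  frac_above <- rowMeans(x > params$filter_min_intensity)
  iqr <- apply(x, 1, IQR)
  keep <- frac_above >= params$filter_min_fraction & iqr >= params$filter_min_iqr
  log_note("non-specific filter: kept %d of %d genes", sum(keep), nrow(x))
  if (!any(keep)) stop_fmt("non-specific filter removed every gene")
  x[keep, , drop = FALSE]
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); returns Inf when x is ~0 (all gene variances essentially equal).
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < tol) break
  }
  y
}

#' Fit the scaled-F prior for gene-level variances
#'
#' Empirical-Bayes moment matching on `log(s2)`: with residual variances
#' `s2` on `df` degrees of freedom, the prior `s2_g ~ s0^2 * d0 / chi^2_d0`
#' has closed-form moment equations in `e = log(s2) - digamma(df/2) +
#' log(df/2)`; the prior df `d0` solves
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` (trigamma inversion by Newton,
#' tolerance 1e-8) and falls back to `d0 = Inf` when the right side is
#' non-positive (no excess variability: all gene variances alike).
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list `d0` (prior df, possibly `Inf`) and `s02` (prior variance).
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(df >= 1, all(s2 >= 0))
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  ev <- sum((e - ebar)^2) / (n - 1) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Shrink per-gene variances toward the prior: s_post^2 =
# (d0*s02 + df*s2)/(d0 + df); d0 = 0 returns s2, d0 = Inf returns s02.
posterior_variances <- function(s2, df, d0, s02) {
  if (!is.finite(d0)) return(rep(s02, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s02 + df * s2) / (d0 + df)
}

#' Case-control differential expression with a moderated t-statistic
#'
#' Two-group contrast (case minus control) per gene with empirical-Bayes
#' variance moderation: the pooled residual variance of each gene is shrunk
#' toward a global prior fitted by [fit_variance_prior()], the t-statistic
#' uses the shrunken SD and gains `d0` prior degrees of freedom. With
#' `use_moderation = FALSE` this is the ordinary equal-variance two-sample
#' t-test.
#'
#' @param x (filtered) expression matrix, log2 scale.
#' @param samples sample table with >= 2 samples per group.
#' @param params [diffexpr_params()].
#' @return data.frame of class `de_result`: `gene`, `logFC` (case -
#'   control), `s` (ordinary residual SD), `s_post`, `t`, `df_total`, `p`,
#'   `q` (BH-FDR), `direction`; attributes `d0` and `s02` carry the fitted
#'   prior.
#' @export
moderated_t <- function(x, samples, params = diffexpr_params()) {
  validate_expression_matrix(x)
  samples <- sample_table(samples)
  idx <- match(samples$sample_id, colnames(x))
  if (anyNA(idx)) {
    stop_fmt("sample(s) missing from expression matrix: %s",
             paste(samples$sample_id[is.na(idx)], collapse = ", "))
  }
  ctrl <- idx[samples$group == "control"]
  case <- idx[samples$group == "case"]
  n1 <- length(ctrl); n2 <- length(case)
  if (n1 < 2 || n2 < 2) stop_fmt("need >= 2 samples per group (have %d/%d)", n1, n2)

  m1 <- rowMeans(x[, ctrl, drop = FALSE])
  m2 <- rowMeans(x[, case, drop = FALSE])
  ss1 <- rowSums((x[, ctrl, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, case, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  logfc <- m2 - m1

  if (params$use_moderation) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0; s02 <- prior$s02
    s2_post <- posterior_variances(s2, dg, d0, s02)
    df_total <- d0 + dg
  } else {
    d0 <- 0; s02 <- NA_real_
    s2_post <- s2
    df_total <- dg
  }
  tstat <- logfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = if (is.finite(df_total)) df_total else Inf)
  res <- data.frame(gene = rownames(x), logFC = logfc, s = sqrt(s2),
                    s_post = sqrt(s2_post), t = tstat,
                    df_total = df_total, p = p, q = bh_fdr(p),
                    direction = ifelse(logfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' Genes with unadjusted `p < alpha`, tagged by fold-change direction.
#' The declaration threshold is deliberately the raw p-value (the FDR
#' q-value is still carried along in the result table).
#'
#' @param res a [moderated_t()] result.
#' @param alpha significance threshold in (0, 1).
#' @return data.frame `gene`, `logFC`, `p`, `direction`, ordered by p.
#' @export
select_degs <- function(res, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  out <- res[res$p < alpha, c("gene", "logFC", "p", "direction")]
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Intersect DEGs with a disease gene panel
#'
#' @param degs [select_degs()] output (needs `gene` and `direction`).
#' @param disease_genes character vector of panel symbols.
#' @return list `up`, `down` (alphabetical symbol vectors) and `counts`
#'   (named: up, down, total).
#' @export
intersect_disease_genes <- function(degs, disease_genes) {
  hit <- degs[degs$gene %in% disease_genes, ]
  up <- sort_c(hit$gene[hit$direction == "up"])
  down <- sort_c(hit$gene[hit$direction == "down"])
  list(up = up, down = down,
       counts = c(up = length(up), down = length(down),
                  total = length(up) + length(down)))
}
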