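#' Welch two-sample t-test from summary statistics
#'
#' Reconstructs the unequal-variance (Welch) t-test from per-group mean, SD
#' and n, as needed when only a published summary table is available:
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)`, degrees of freedom by
#' Welch-Satterthwaite, two-sided p from the Student-t tail.
#'
#' Degenerate inputs: both SDs zero with equal means gives `t = 0, p = 1`;
#' both SDs zero with different means gives `p = 0` with a warning.
#'
#' @param mean1,sd1,n1 group 1 summary (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 group 2 summary.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    warn_fmt("zero variance in both groups with unequal means; p = 0")
    return(list(t = sign(mean2 - mean1) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Group-comparison table for intermediate traits
#'
#' One row per trait (per sex stratum when `stratify_by_sex = TRUE`):
#' mean, SD and n in each group plus the Welch two-sided p-value. A trait
#' with fewer than two non-missing values in either compared cell gets
#' `p = NA` (marked unavailable) but its summaries are still emitted.
#'
#' @param samples a [sample_table()] with numeric trait columns.
#' @param stratify_by_sex compare within each sex separately.
#' @return data.frame: `trait`, optional `sex`, `mean_control`,
#'   `sd_control`, `n_control`, `mean_case`, `sd_case`, `n_case`, `t`,
#'   `df`, `p`.
#' @export
trait_table <- function(samples, stratify_by_sex = FALSE) {
  samples <- sample_table(samples)
  strata <- if (stratify_by_sex) {
    if (!"sex" %in% names(samples)) stop_fmt("no 'sex' column to stratify by")
    split(samples, samples$sex)
  } else list(all = samples)
  rows <- list()
  for (sx in names(strata)) {
    dat <- strata[[sx]]
    for (tr in trait_names(samples)) {
      v1 <- dat[[tr]][dat$group == "control"]
      v2 <- dat[[tr]][dat$group == "case"]
      v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
      row <- data.frame(trait = tr,
                        mean_control = if (length(v1)) mean(v1) else NA_real_,
                        sd_control = if (length(v1) > 1) sd(v1) else NA_real_,
                        n_control = length(v1),
                        mean_case = if (length(v2)) mean(v2) else NA_real_,
                        sd_case = if (length(v2) > 1) sd(v2) else NA_real_,
                        n_case = length(v2),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
      if (stratify_by_sex) row <- cbind(sex = sx, row)
      if (length(v1) >= 2 && length(v2) >= 2) {
        w <- welch_t_from_summary(mean(v1), sd(v1), length(v1),
                                  mean(v2), sd(v2), length(v2))
        row$t <- w$t; row$df <- w$df; row$p <- w$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch p-values recomputed from a published summary table
#'
#' For summary tables printed as mean +/- SD per group (optionally per sex
#' stratum): expects columns `trait`, `mean_control`, `sd_control`,
#' `mean_case`, `sd_case` and optionally `n_control`/`n_case` (defaulting
#' to `n_default`, e.g. 15 per sex stratum in a 30 + 30 cohort with a 1:1
#' sex ratio).
#'
#' @param summaries data.frame of printed summaries.
#' @param n_default per-cell n used when the table does not print one.
#' @return input with `t`, `df`, `p` columns appended.
#' @export
trait_table_from_summary <- function(summaries, n_default = 15) {
  need <- c("trait", "mean_control", "sd_control", "mean_case", "sd_case")
  if (!all(need %in% names(summaries))) {
    stop_fmt("summary table needs columns: %s", paste(need, collapse = ", "))
  }
  n1 <- summaries$n_control %||% rep(n_default, nrow(summaries))
  n2 <- summaries$n_case %||% rep(n_default, nrow(summaries))
  res <- lapply(seq_len(nrow(summaries)), function(i)
    welch_t_from_summary(summaries$mean_control[i], summaries$sd_control[i], n1[i],
                         summaries$mean_case[i], summaries$sd_case[i], n2[i]))
  summaries$t <- vapply(res, `[[`, numeric(1), "t")
  summaries$df <- vapply(res, `[[`, numeric(1), "df")
  summaries$p <- vapply(res, `[[`, numeric(1), "p")
  summaries
}
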