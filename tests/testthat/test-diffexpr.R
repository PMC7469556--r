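test_that("non-specific filter removes low-information genes", {
  x <- tiny_expression(g = 6, s = 8)
  x[5, ] <- 5                               # constant: IQR 0
  x[6, ] <- c(5, 5, 5, 5, 5, 5, 5, 9)
  expect_identical(suppressMessages(nonspecific_filter(x)), x)  # thresholds 0
  f <- suppressMessages(
    nonspecific_filter(x, diffexpr_params(filter_min_iqr = 0.1)))
  expect_false("G05" %in% rownames(f))
  f2 <- suppressMessages(nonspecific_filter(
    x, diffexpr_params(filter_min_intensity = 6, filter_min_fraction = 0.5)))
  expect_false(any(c("G05", "G06") %in% rownames(f2)))
  expect_error(suppressMessages(nonspecific_filter(
    x, diffexpr_params(filter_min_intensity = 100, filter_min_fraction = 1))),
    "every gene")
})

test_that("filter separates planted near-constant genes exactly", {
  set.seed(31)
  n <- 1000
  x <- matrix(rnorm(n * 20, 8, 1), nrow = n,
              dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:20)))
  flat <- sample(rownames(x), 100)
  x[flat, ] <- 8 + matrix(rnorm(100 * 20, 0, 0.01), nrow = 100)
  kept <- suppressMessages(nonspecific_filter(
    expression_matrix(x), diffexpr_params(filter_min_iqr = 0.3)))
  expect_setequal(setdiff(rownames(x), rownames(kept)), flat)
})

test_that("moderated t matches the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  n1 <- 8; n2 <- 8; g <- 400
  sds <- sqrt(1 / rgamma(g, 4, 4 * 0.25))   # heteroscedastic gene variances
  x <- expression_matrix(matrix(rnorm(g * (n1 + n2), 8, sds), nrow = g,
                                dimnames = list(sprintf("g%03d", 1:g),
                                                sprintf("s%02d", 1:(n1 + n2)))))
  smp <- two_group_samples(n1, n2)
  colnames(x) <- smp$sample_id
  res <- moderated_t(x, smp)
  fit <- limma::eBayes(limma::lmFit(x, stats::model.matrix(
    ~ rep(0:1, c(n1, n2)))))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("moderation limits: d0 -> 0 is the ordinary t, d0 -> Inf pools to s0", {
  x <- tiny_expression(g = 10, s = 12, seed = 2)
  smp <- two_group_samples(6, 6)
  colnames(x) <- smp$sample_id
  plain <- moderated_t(x, smp, diffexpr_params(use_moderation = FALSE))
  s2 <- plain$s^2
  expect_equal(posterior_variances_limit <- adipolink:::posterior_variances(
    s2, 10, 0, 0.4), s2)
  expect_equal(adipolink:::posterior_variances(s2, 10, Inf, 0.4),
               rep(0.4, 10))
  # unmoderated result equals t.test with pooled variance
  ref <- apply(x, 1, function(v)
    t.test(v[7:12], v[1:6], var.equal = TRUE)$p.value)
  expect_equal(plain$p, unname(ref), tolerance = 1e-12)
})

test_that("variance prior fit falls back to d0 = Inf for equal variances", {
  fit <- fit_variance_prior(rep(0.25, 50), df = 10)
  expect_false(is.finite(fit$d0))
  expect_equal(fit$s02, exp(log(0.25) - digamma(5) + log(5)))
})

test_that("planted DE recovery: high sensitivity at the default threshold", {
  cfg <- sim_config(n_genes = 2000, n_de = 100, de_effect = 1.0,
                    sigma_gene = 0.5, seed = 17)
  sim <- suppressMessages(simulate_dataset(cfg))
  res <- moderated_t(sim$expression, sim$samples)
  degs <- select_degs(res, 0.05)
  sens <- mean(sim$truth$de_genes$gene %in% degs$gene)
  expect_gte(sens, 0.9)
  # direction tags agree with planted signs
  hit <- merge(degs, sim$truth$de_genes, by = "gene")
  expect_true(all((hit$effect > 0) == (hit$direction == "up")))
})

test_that("select_degs respects alpha bounds and ordering", {
  x <- tiny_expression(g = 20, s = 10, seed = 5)
  smp <- two_group_samples(5, 5)
  colnames(x) <- smp$sample_id
  res <- moderated_t(x, smp)
  expect_equal(nrow(select_degs(res, 1)), 20)
  expect_equal(nrow(select_degs(res, 1e-300)), 0)
  d <- select_degs(res, 0.5)
  expect_false(is.unsorted(d$p))
})

test_that("disease-gene intersection splits by direction deterministically", {
  degs <- data.frame(gene = c("Z", "A", "M", "B"),
                     logFC = c(1, -1, 2, -2), p = c(0.01, 0.02, 0.03, 0.04),
                     direction = c("up", "down", "up", "down"))
  out <- intersect_disease_genes(degs, c("A", "M", "Z", "Q"))
  expect_identical(out$up, c("M", "Z"))
  expect_identical(out$down, "A")
  expect_equal(unname(out$counts), c(2, 1, 3))
  empty <- intersect_disease_genes(degs, "NOPE")
  expect_equal(unname(empty$counts["total"]), 0)
  allup <- intersect_disease_genes(degs[degs$direction == "up", ],
                                   c("Z", "M"))
  expect_identical(allup$up, c("M", "Z"))
  expect_length(allup$down, 0)
})

test_that("moderated p is monotone in |t| and errors on tiny groups", {
  x <- tiny_expression(g = 30, s = 10, seed = 6)
  smp <- two_group_samples(5, 5)
  colnames(x) <- smp$sample_id
  res <- moderated_t(x, smp)
  o <- order(abs(res$t))
  expect_false(is.unsorted(rev(res$p[o])))
  smp_bad <- two_group_samples(1, 9)
  colnames(x) <- smp_bad$sample_id
  expect_error(moderated_t(x, smp_bad), ">= 2 samples")
})
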