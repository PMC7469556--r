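test_that("soft adjacency: identical genes, beta = 1, and the power formula", {
  set.seed(1)
  s <- 8
  base <- rnorm(s)
  x <- expression_matrix(rbind(g1 = 8 + base, g2 = 8 + base,
                               g3 = 8 + rnorm(s)),
                         sample_ids = sprintf("s%d", 1:s))
  a1 <- soft_adjacency(x, beta = 7)
  expect_equal(a1["g1", "g2"], 1)
  a2 <- soft_adjacency(x, beta = 1)
  expect_equal(a2["g1", "g3"], abs(cor(x["g1", ], x["g3", ])))
  expect_true(all(diag(a1) == 0))
  expect_equal(a1["g1", "g3"], a2["g1", "g3"]^7)    # power map consistency
  expect_error(soft_adjacency(x[, 1:2, drop = FALSE]), ">= 3 samples")
  x[3, ] <- 5
  expect_warning(az <- soft_adjacency(x, beta = 6), "zero-variance")
  expect_false("g3" %in% rownames(az))
})

test_that("TOM formula: hand case, isolated pair, clique saturation", {
  a <- matrix(c(0, 0.8, 0.5,
                0.8, 0, 0.4,
                0.5, 0.4, 0), nrow = 3,
              dimnames = rep(list(c("x", "y", "z")), 2))
  tom <- tom_similarity(a)
  expect_equal(tom["x", "y"], (0.5 * 0.4 + 0.8) / (min(1.3, 1.2) + 1 - 0.8),
               tolerance = 1e-12)
  expect_equal(tom["x", "y"], 0.714286, tolerance = 1e-6)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1))

  iso <- matrix(0, 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_equal(tom_similarity(iso)["a", "b"], 0)

  clique <- matrix(1, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  diag(clique) <- 0
  tc <- tom_similarity(clique)
  expect_true(all(tc == 1))
})

test_that("scale-free fit: power-law sequence scores high, flat is undefined", {
  # connectivity sequence whose bin frequencies follow p(k) ~ k^-2.2 exactly
  k <- unlist(lapply(1:10, function(j) rep(10 * j, round(500 * j^-2.2))))
  m <- length(k)
  a <- matrix(k / m, m, m)                   # constant rows: rowSums = k
  dimnames(a) <- rep(list(sprintf("g%04d", 1:m)), 2)
  fit <- scale_free_fit(a)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)

  flat <- matrix(0.5, 12, 12, dimnames = rep(list(sprintf("f%02d", 1:12)), 2))
  diag(flat) <- 0
  f2 <- scale_free_fit(flat)
  expect_true(is.na(f2$r_squared))
})

test_that("module detection: planted blocks, identical genes, pure noise", {
  sim <- suppressMessages(simulate_dataset(
    sim_config(n_genes = 300, n_de = 0, n_de_disease = 0, seed = 6)))
  sub <- sim$expression[sim$truth$disease_genes, ]
  asn <- detect_modules(tom_similarity(soft_adjacency(sub, 15)))
  non_grey <- setdiff(unique(asn), "grey")
  expect_length(non_grey, 2)
  expect_identical(sort(unique(asn)),
                   sort(c("turquoise", "blue", "grey")))
  # planted blocks map to the detected modules with high purity
  for (b in names(sim$truth$modules)) {
    lab <- asn[sim$truth$modules[[b]]]
    expect_gte(max(table(lab)[non_grey], na.rm = TRUE), 27)
  }

  # all genes identical -> one turquoise module
  set.seed(8)
  s <- 10
  base <- rnorm(s)
  same <- expression_matrix(matrix(rep(8 + base, each = 12), nrow = 12,
                                   dimnames = list(sprintf("g%02d", 1:12),
                                                   sprintf("s%02d", 1:s))))
  asn_same <- detect_modules(tom_similarity(soft_adjacency(same, 15)))
  expect_true(all(asn_same == "turquoise"))

  # independent genes stay grey under a strong power
  set.seed(9)
  noise <- expression_matrix(matrix(rnorm(40 * 30, 8, 0.5), nrow = 40,
                                    dimnames = list(sprintf("n%02d", 1:40),
                                                    sprintf("s%02d", 1:30))))
  asn_noise <- detect_modules(tom_similarity(soft_adjacency(noise, 15)))
  expect_true(all(asn_noise == "grey"))
})

test_that("eigengenes: degenerate module, unit variance, sign invariance", {
  s <- 12
  set.seed(14)
  base <- rnorm(s)
  x <- expression_matrix(rbind(
    g1 = 8 + base, g2 = 8 + base, g3 = 8 + base,
    g4 = 8 + rnorm(s), g5 = 8 + rnorm(s)),
    sample_ids = sprintf("s%02d", 1:s))
  asn <- setNames(c("turquoise", "turquoise", "turquoise", "grey", "grey"),
                  rownames(x))
  mes <- module_eigengenes(x, asn)
  expect_equal(sd(mes[, "MEturquoise"]), 1)
  # identical genes: ME is the standardized common profile
  expect_equal(unname(mes[, "MEturquoise"]),
               unname((base - mean(base)) / sd(base)), tolerance = 1e-8)
  # flipping all module genes leaves |cor(ME, trait)| unchanged
  x2 <- x
  x2[1:3, ] <- 16 - x2[1:3, ]
  mes2 <- module_eigengenes(x2, asn)
  trait <- rnorm(s)
  expect_equal(abs(cor(mes[, 1], trait)), abs(cor(mes2[, 1], trait)),
               tolerance = 1e-8)
  # single-gene module warns and returns the standardized gene
  asn1 <- setNames(c("blue", rep("grey", 4)), rownames(x))
  expect_warning(m1 <- module_eigengenes(x, asn1), "single gene")
  expect_equal(unname(m1[, "MEblue"]),
               unname((x[1, ] - mean(x[1, ])) / sd(x[1, ])))
})

test_that("eigengene variance explained follows the single-factor prediction", {
  set.seed(33)
  loading <- 0.8; m <- 30; s <- 1000
  f <- rnorm(s)
  x <- expression_matrix(
    8 + loading * matrix(f, m, s, byrow = TRUE) +
      sqrt(1 - loading^2) * matrix(rnorm(m * s), m, s),
    gene_ids = sprintf("g%02d", 1:m), sample_ids = sprintf("s%03d", 1:s))
  std <- t(scale(t(x)))
  pc <- prcomp(t(std), center = FALSE)
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  expect_lt(abs(ve - (loading^2 + (1 - loading^2) / m)), 0.03)
})

test_that("module-trait correlation: self-trait, closed form, missing data", {
  set.seed(44)
  s <- 30
  base <- rnorm(s)
  x <- expression_matrix(matrix(rep(8 + 0.5 * base, each = 10), nrow = 10,
                                dimnames = list(sprintf("g%02d", 1:10),
                                                sprintf("s%02d", 1:s))))
  asn <- setNames(rep("turquoise", 10), rownames(x))
  mes <- module_eigengenes(x, asn)
  smp <- data.frame(sample_id = colnames(x),
                    group = rep(c("control", "case"), each = 15),
                    self = as.numeric(mes[, 1]),
                    const = 1,
                    holey = replace(rnorm(s), 1:10, NA))
  mt <- module_trait_relationships(mes, smp)
  self_row <- mt[mt$trait == "self", ]
  expect_equal(self_row$r, 1, tolerance = 1e-12)
  expect_equal(self_row$p, 0)
  expect_true(is.na(mt$r[mt$trait == "const"]))
  expect_equal(mt$n[mt$trait == "holey"], 20)
  # closed-form check: r = 0.5, n = 30 -> t = 3.055, p ~ 0.0049
  r <- 0.5; n <- 30
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tstat, 3.05505, tolerance = 1e-4)
  expect_equal(2 * pt(-tstat, n - 2), 0.004899934, tolerance = 1e-6)
})

test_that("per-group pipeline is deterministic and isolated between groups", {
  sim <- suppressMessages(simulate_dataset(
    sim_config(n_genes = 300, n_de = 0, n_de_disease = 0, seed = 51)))
  a <- suppressMessages(coexpression_group(sim$expression, sim$samples,
                                           sim$truth$disease_genes, "control"))
  b <- suppressMessages(coexpression_group(sim$expression, sim$samples,
                                           sim$truth$disease_genes, "control"))
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$eigengenes, b$eigengenes)
  cs <- suppressMessages(coexpression_group(sim$expression, sim$samples,
                                            sim$truth$disease_genes, "case"))
  expect_equal(nrow(cs$eigengenes),
               sum(sim$samples$group == "case"))
})
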