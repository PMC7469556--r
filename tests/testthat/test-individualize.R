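test_that("control envelope: hand arithmetic, flooring, absent genes", {
  x <- expression_matrix(matrix(c(7, 9, 8, 8.5,
                                  8, 8, 8, 8), nrow = 2, byrow = TRUE,
                                dimnames = list(c("gA", "gB"),
                                                c("c1", "c2", "t1", "t2"))))
  smp <- sample_table(data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                                 group = c("control", "control", "case", "case")))
  expect_warning(env <- control_envelope(x, smp, c("gA", "gB")), "floored")
  expect_equal(env$mean[env$gene == "gA"], 8)
  expect_equal(env$sd[env$gene == "gA"], sqrt(2))   # n - 1 denominator
  expect_equal(env$sd[env$gene == "gB"], 1e-6)      # zero SD floored
  expect_message(env2 <- suppressWarnings(
    control_envelope(x, smp, c("gA", "gB", "gZ"))), "absent")
  expect_setequal(env2$gene, c("gA", "gB"))
  one_ctrl <- smp; one_ctrl$group <- c("control", "case", "case", "case")
  expect_error(control_envelope(x, one_ctrl, "gA"), ">= 2 control")
})

test_that("flag rule: sd and fold modes on a constructed case", {
  # control mu = 8, sd = 0.5; case value 9.2
  set.seed(61)
  ctrl_vals <- c(7.5, 8.5, 8.0, 7.6, 8.4)        # mean 8, sd ~ 0.45
  ctrl_vals <- 8 + (ctrl_vals - mean(ctrl_vals)) / sd(ctrl_vals) * 0.5
  x <- expression_matrix(matrix(c(ctrl_vals, 9.2, 8.0), nrow = 1,
                                dimnames = list("gA", sprintf("s%d", 1:7))))
  smp <- sample_table(data.frame(sample_id = sprintf("s%d", 1:7),
                                 group = rep(c("control", "case"), c(5, 2))))
  env <- control_envelope(x, smp, "gA")
  expect_equal(env$sd, 0.5)
  f_sd <- flag_patient_genes(x, smp, env, individualization_params("sd", 2))
  expect_identical(f_sd$per_patient$s6$up, "gA")   # 1.2 > 2 * 0.5
  expect_length(f_sd$per_patient$s7$up, 0)
  f_fold <- flag_patient_genes(x, smp, env, individualization_params("fold", 2))
  expect_identical(f_fold$per_patient$s6$up, "gA") # 1.2 > log2(2)
  # patient identical to the control mean is never flagged
  expect_length(unlist(f_sd$per_patient$s7), 0)
})

test_that("raising the threshold never adds a flag (nested envelopes)", {
  sim <- suppressMessages(simulate_dataset(sim_config(n_genes = 300, seed = 71)))
  env <- suppressWarnings(suppressMessages(control_envelope(
    sim$expression, sim$samples, sim$truth$disease_genes)))
  key <- function(f) paste(f$flags$sample_id, f$flags$gene, f$flags$direction)
  prev <- NULL
  for (th in c(1.5, 2, 2.5, 3, 4)) {
    fl <- key(flag_patient_genes(sim$expression, sim$samples, env,
                                 individualization_params("sd", th)))
    if (!is.null(prev)) expect_true(all(fl %in% prev))
    prev <- fl
  }
})

test_that("sd and fold modes coincide when sigma_c = log2(fold)/k_sd", {
  # control sample SD exactly 0.5 makes both envelopes |x - mu| > 1 at the
  # default thresholds (2 SD vs 2-fold on log2 scale)
  d <- 0.5 * sqrt(3) / 2                  # +/- d around 8 has sample SD 0.5
  vals <- c(8 - d, 8 + d, 8 - d, 8 + d, 9.05, 8.95, 6.9, 7.05)
  x <- expression_matrix(matrix(vals, nrow = 1,
                                dimnames = list("g", sprintf("s%d", 1:8))))
  smp <- sample_table(data.frame(sample_id = sprintf("s%d", 1:8),
                                 group = rep(c("control", "case"), each = 4)))
  env <- control_envelope(x, smp, "g")
  expect_equal(env$sd, 0.5)
  a <- flag_patient_genes(x, smp, env, individualization_params("sd", 2))
  b <- flag_patient_genes(x, smp, env, individualization_params("fold", 2))
  expect_identical(a$flags, b$flags)
  expect_identical(a$per_patient$s5$up, "g")     # 1.05 above the envelope
  expect_identical(a$per_patient$s7$down, "g")   # 1.10 below
  expect_length(unlist(a$per_patient$s6), 0)     # 0.95 inside
  expect_length(unlist(a$per_patient$s8), 0)
})

test_that("planted outliers are recovered exactly with Gaussian-rate extras", {
  spec <- data.frame(sample_id = rep(c("CASE02", "CASE09", "CASE17"), 2:4),
                     gene = c("G00010", "G00011", "G00012", "G00020", "G00021",
                              "G00030", "G00031", "G00032", "G00033"),
                     shift = c(3, -3, 3.5, 3, -3.5, 3, 3, -3, 4))
  cfg <- sim_config(n_genes = 400, n_de = 0, n_de_disease = 0,
                    outlier_spec = spec, seed = 81)
  sim <- suppressMessages(simulate_dataset(cfg))
  env <- suppressMessages(control_envelope(sim$expression, sim$samples,
                                           sim$truth$disease_genes))
  fl <- flag_patient_genes(sim$expression, sim$samples, env,
                           individualization_params("sd", 2))
  planted <- paste(spec$sample_id, spec$gene)
  flagged <- paste(fl$flags$sample_id, fl$flags$gene)
  expect_true(all(planted %in% flagged))
  # directions match planted signs
  pl <- merge(fl$flags, spec, by = c("sample_id", "gene"))
  expect_true(all((pl$shift > 0) == (pl$direction == "up")))
  # per-cell null flag rate with a 30-control estimated envelope: the
  # deviation is t-distributed, |t_29| > 2*sqrt(30/31), whose rate 5.9%
  # tends to the Gaussian 2*Phi(-2) ~ 4.6% as controls grow. Shared
  # per-gene envelope estimates correlate cells, so the band propagates
  # both the within-gene binomial and the between-gene sigma-hat variance.
  n_ctrl <- 30
  p0 <- 2 * pt(-2 / sqrt(1 + 1 / n_ctrl), n_ctrl - 1)
  sd_r <- 1 / sqrt(2 * (n_ctrl - 1))           # sd of sigma-hat/sigma
  dq <- 2 * dnorm(2 / sqrt(1 + 1 / n_ctrl)) * 2 / sqrt(1 + 1 / n_ctrl)
  n_genes_panel <- 138
  var_f <- p0 * (1 - p0) / 30 + (dq * sd_r)^2
  tol <- 4 * sqrt(var_f / n_genes_panel)
  n_cells <- 138 * 30 - nrow(spec)
  fp <- sum(!flagged %in% planted)
  expect_lt(abs(fp / n_cells - p0), tol)

  fs <- frequency_summary(fl)
  expect_gte(fs$patients_with_any, 3)
  top <- fs$frequency
  expect_false(is.unsorted(rev(top$n_patients)))
})

test_that("frequency summary counts patients per gene and empty input", {
  empty <- structure(list(flags = data.frame(sample_id = character(),
                                             gene = character(),
                                             direction = character(),
                                             deviation = numeric()),
                          per_patient = list(),
                          params = individualization_params()),
                     class = "patient_flags")
  fs <- frequency_summary(empty)
  expect_equal(fs$patients_with_any, 0)
  expect_equal(nrow(fs$frequency), 0)

  flags <- structure(list(flags = data.frame(
    sample_id = c("p1", "p2", "p3", "p1"),
    gene = c("gA", "gA", "gA", "gB"),
    direction = c("up", "down", "up", "up"),
    deviation = c(1.2, -1.3, 1.1, 1.4)),
    per_patient = list(), params = individualization_params()),
    class = "patient_flags")
  fs2 <- frequency_summary(flags)
  expect_equal(fs2$frequency$n_patients[fs2$frequency$gene == "gA"], 3)
  expect_equal(fs2$patients_with_any, 3)
})

test_that("missing case samples in the matrix are a named hard error", {
  x <- tiny_expression(g = 3, s = 4)
  smp <- sample_table(data.frame(sample_id = c(colnames(x)[1:2], "GHOST", "S04"),
                                 group = c("control", "control", "case", "case")))
  env <- suppressMessages(control_envelope(x, smp, rownames(x)))
  expect_error(flag_patient_genes(x, smp, env, individualization_params()),
               "GHOST")
})
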