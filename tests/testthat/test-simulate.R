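two_batch_params <- function(n_genes, alpha, beta, sigma, gamma = 0,
                             delta2 = 1) {
  ls_model_params(
    alpha = rep_len(alpha, n_genes), beta = rep_len(beta, n_genes),
    sigma = rep_len(sigma, n_genes),
    gamma = matrix(gamma, 2, n_genes, dimnames = list(c("B1", "B2"), NULL)),
    delta2 = matrix(delta2, 2, n_genes, dimnames = list(c("B1", "B2"), NULL)),
    treatment_level = "case")
}

test_that("the L/S engine reproduces its generative law", {
  # noise-free limit: values are exactly alpha + x * beta
  sheet <- toy_sheet(8, c("B1", "B2"), c("case", "control"))
  p <- two_batch_params(5, alpha = 7, beta = 2, sigma = 0)
  y <- sample_ls_model(p, sheet, seed = 1)
  x <- as.numeric(sheet$group == "case")
  expect_equal(unname(y), outer(rep(7, 5), rep(1, 8)) + outer(rep(2, 5), x))

  # Monte-Carlo: single gene, two groups of 1e4, beta = 1
  n <- 10000L
  sheet2 <- data.frame(sample_id = sprintf("s%05d", 1:(2 * n)),
                       batch = "B1",
                       group = rep(c("case", "control"), each = n))
  p2 <- ls_model_params(alpha = c(5, 5), beta = c(1, 1), sigma = c(1, 1),
                        gamma = matrix(0, 1, 2, dimnames = list("B1", NULL)),
                        delta2 = matrix(1, 1, 2, dimnames = list("B1", NULL)),
                        treatment_level = "case")
  y2 <- sample_ls_model(p2, sheet2, seed = 7)
  dif <- mean(y2[1, sheet2$group == "case"]) -
    mean(y2[1, sheet2$group == "control"])
  expect_lt(abs(dif - 1), 4 * sqrt(2 / n))

  # per-batch means shift by gamma = (+c, -c); per-batch sd -> delta * sigma
  cval <- 0.8
  sheet3 <- data.frame(sample_id = sprintf("s%05d", 1:(2 * n)),
                       batch = rep(c("B1", "B2"), each = n),
                       group = "control")
  p3 <- two_batch_params(1, alpha = 6, beta = 0, sigma = 0.5,
                         gamma = c(cval, -cval), delta2 = c(4, 4))
  y3 <- sample_ls_model(p3, sheet3, seed = 3)
  m1 <- mean(y3[1, sheet3$batch == "B1"])
  m2 <- mean(y3[1, sheet3$batch == "B2"])
  se_m <- 2 * 0.5 / sqrt(n)
  expect_lt(abs((m1 - m2) - 2 * cval), 4 * sqrt(2) * se_m)
  s1 <- sd(y3[1, sheet3$batch == "B1"])
  expect_lt(abs(s1 - 2 * 0.5), 4 * (2 * 0.5) / sqrt(2 * n))

  expect_error(sample_ls_model(p3, toy_sheet(4, "B9", "control"), seed = 1),
               "B9")
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_vas(seed = 5, n_genes = 60L)
  b <- simulate_vas(seed = 5, n_genes = 60L)
  expect_identical(a$expr_single, b$expr_single)
  expect_identical(a$expr_batched, b$expr_batched)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$expr_batched, simulate_vas(seed = 6, n_genes = 60L)$expr_batched))

  s1 <- simulate_aas(seed = 9, n_genes = 240L, n_de = 24L)
  s2 <- simulate_aas(seed = 9, n_genes = 240L, n_de = 24L)
  expect_identical(s1$expr, s2$expr)
})

test_that("VAS design: 65/35 profiles, shared truth, duplicate structure", {
  sim <- simulate_vas(seed = 2, n_genes = 120L)
  expect_equal(unname(table(sim$sheet$group)[c("Profile1", "Profile2")]),
               c(65L, 35L), ignore_attr = TRUE)
  expect_identical(dimnames(sim$expr_single), dimnames(sim$expr_batched))
  expect_true(all(sim$truth$is_de))
  expect_true(all(abs(sim$truth$nominal_log2_fc) >= min(abs(FC_LEVELS))))
  expect_true(all(sim$truth$nominal_log2_fc %in% FC_LEVELS))
  # both batches contain both profiles (not confounded)
  expect_true(all(table(sim$sheet$batch, sim$sheet$group) > 0))
})

test_that("VAS replicates without injected batch effects behave identically", {
  spec <- batch_effect_spec(gamma_sd = 0, delta_fixed = 1)
  sim <- simulate_vas(spec, seed = 3, n_genes = 200L)
  r <- replicate_gene_correlation(
    standardize_genes(sim$expr_single), standardize_genes(sim$expr_batched))
  expect_gt(median(r), 0)
  pv <- pvca(sim$expr_batched, sim$sheet, threshold = 0.6)
  expect_lt(pv$weighted_proportions["batch"], 0.02)
})

test_that("AAS design: truth bookkeeping matches the design exactly", {
  sim <- simulate_aas(seed = 1)      # full 10,000-gene design
  expect_equal(sum(sim$truth$is_de), 1200L)
  expect_equal(sum(!sim$truth$is_de), 8800L)
  lv <- sort(unique(sim$truth$nominal_log2_fc[sim$truth$is_de]))
  expect_equal(lv, sort(FC_LEVELS))
  expect_equal(lv, -rev(lv))          # symmetric about 0
  expect_true(all(table(sim$truth$nominal_log2_fc[sim$truth$is_de]) == 100L))
  expect_true(all(sim$truth$nominal_log2_fc[!sim$truth$is_de] == 0))

  # generative expectation: genes at nominal level 1.0 average ~1.0 observed
  obs <- observed_log2_fc(sim$expr, sim$sheet, levels = c("control", "case"))
  at1 <- obs[sim$truth$nominal_log2_fc == 1]
  expect_lt(abs(mean(at1) - 1), 4 * sd(at1) / sqrt(length(at1)))

  expect_error(
    simulate_aas(layout = data.frame(batch = "B1", n_case = 50,
                                     n_control = 50)),
    "must sum")
})

test_that("confounded design aligns batch with case status", {
  sim <- simulate_confounded(seed = 4, n_genes = 600L, n_de = 72L)
  expect_true(all(sim$sheet$batch[sim$sheet$group == "case"] == "B1"))
  expect_true(all(sim$sheet$batch[sim$sheet$group == "control"] == "B2"))
  expect_error(ratio_g(sim$expr, sim$sheet), "B1")

  # no-batch-effect limit: the case/control signal is pure beta and a DE
  # test recovers most of the DE genes
  clean <- simulate_confounded(batch_effect_spec(gamma_sd = 0,
                                                 delta_fixed = 1),
                               seed = 4, n_genes = 600L, n_de = 72L)
  p <- de_pvalues(clean$expr, clean$sheet,
                  levels = c("control", "case"))$p_value
  expect_gt(sum(p[clean$truth$is_de] < 0.05) / 72, 0.75)
})

test_that("simulations round-trip through their TSV writers", {
  sim <- simulate_aas(seed = 6, n_genes = 50L, n_de = 12L)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_equal(read_expression_tsv(file.path(dir, "expr.tsv")), sim$expr,
               tolerance = 1e-12)
  expect_equal(read_sample_sheet(file.path(dir, "sample_sheet.tsv")),
               sim$sheet)
})
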