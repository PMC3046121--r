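test_that("gene standardization hits its postconditions and is idempotent", {
  sim <- null_sim(n_genes = 80L, seed = 31L)
  z <- standardize_genes(sim$expr)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(standardize_genes(z), z, tolerance = 1e-10)

  # within-stratum mode
  sheet <- sim$sheet
  sheet$replicate_group <- rep_len(c("r1", "r2"), nrow(sheet))
  zz <- standardize_genes(sim$expr, sheet, within = "replicate_group")
  for (s in c("r1", "r2")) {
    sub <- zz[, sheet$replicate_group == s]
    expect_lt(max(abs(rowMeans(sub))), 1e-10)
    expect_lt(max(abs(apply(sub, 1, sd) - 1)), 1e-10)
  }
  # zero-variance gene floored with a warning
  x <- sim$expr
  x[1, ] <- 5
  expect_warning(standardize_genes(x), "zero variance")
})

test_that("standardization kills baseline-driven sample correlations", {
  # large gene-baseline spread, small residual noise: every sample pair
  # correlates > 0.9 before standardization, median ~ 0 after
  sheet <- toy_sheet(30, "B1", c("a", "b"),
                     sample_ids = sprintf("s%03d", 1:30))
  p <- ls_model_params(
    alpha = rnorm(400, 7, 2), beta = rep(0, 400), sigma = rep(0.35, 400),
    gamma = matrix(0, 1, 400, dimnames = list("B1", NULL)),
    delta2 = matrix(1, 1, 400, dimnames = list("B1", NULL)),
    treatment_level = "a")
  x <- sample_ls_model(p, sheet, seed = 44)
  cc <- cor(x)
  expect_gt(min(cc[upper.tri(cc)]), 0.9)
  cs <- cor(standardize_genes(x))
  expect_lt(abs(median(cs[upper.tri(cs)])), 0.05)
})

test_that("replicate correlations behave at the exact limits and match cor()", {
  x <- toy_expr(rnorm(40), 10, 4)
  expect_equal(unname(replicate_gene_correlation(x, x)), rep(1, 10))
  expect_equal(unname(replicate_gene_correlation(x, -x)), rep(-1, 10))
  a <- toy_expr(c(1.2, 3.4, 2.2, 5.0), 1, 4)
  b <- toy_expr(c(0.9, 2.8, 2.9, 4.1), 1, 4)
  expect_equal(unname(replicate_gene_correlation(a, b)),
               cor(a[1, ], b[1, ]))
  expect_error(replicate_gene_correlation(a[, 1:2, drop = FALSE],
                                          b[, 1:2, drop = FALSE]), "3")
})

test_that("per-gene ICC equals the sums-of-squares oracle", {
  make_design <- function(n_subj, k) {
    data.frame(sample_id = sprintf("s%03d", seq_len(n_subj * k)),
               batch = "B1", group = "g",
               subject = rep(sprintf("p%02d", 1:n_subj), k),
               replicate_group = rep(sprintf("r%d", 1:k), each = n_subj))
  }
  sheet <- make_design(3, 3)
  x <- toy_expr(c(10, 11, 10.5, 10.1, 11.2, 10.4, 9.9, 10.8, 10.6), 1, 9,
                sample_ids = sheet$sample_id)
  icc <- icc_per_gene(x, sheet, "replicate_group", "subject")
  expect_equal(unname(icc), icc_oracle(x[1, ], sheet$subject,
                                       sheet$replicate_group))

  # identical replicates per subject: ICC = 1
  y <- toy_expr(rep(rnorm(4), 3), 1, 12, sample_ids = make_design(4, 3)$sample_id)
  expect_equal(unname(icc_per_gene(y, make_design(4, 3),
                                   "replicate_group", "subject")), 1)

  # subject means equal, replicates pure noise: ICC ~ 0 (can dip negative)
  set.seed(6)
  z <- toy_expr(rnorm(5 * 4 * 200), 200, 20,
                gene_ids = sprintf("g%03d", 1:200),
                sample_ids = make_design(5, 4)$sample_id)
  icc0 <- icc_per_gene(z, make_design(5, 4), "replicate_group", "subject")
  expect_lt(abs(median(icc0)), 0.15)

  # property: random complete designs equal the oracle
  for (case in 1:20) {
    set.seed(case)
    ns <- sample(3:8, 1); k <- sample(2:4, 1)
    sh <- make_design(ns, k)
    xx <- toy_expr(rnorm(ns * k * 3), 3, ns * k, sample_ids = sh$sample_id)
    icc <- icc_per_gene(xx, sh, "replicate_group", "subject")
    for (g in 1:3)
      expect_equal(unname(icc[g]),
                   icc_oracle(xx[g, ], sh$subject, sh$replicate_group))
  }

  # incomplete design is refused
  bad <- make_design(3, 2)[-1, ]
  expect_error(icc_per_gene(x[, bad$sample_id, drop = FALSE], bad,
                            "replicate_group", "subject"), "incomplete")
})

test_that("Fisher z is the odd closed form with guarded edges", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1.2), "correlation")
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("the paired z shift test matches exhaustive signed-rank enumeration", {
  z <- rnorm(100)
  expect_equal(paired_z_shift_test(z, z), list(median_diff = 0, p_value = 1))
  res <- paired_z_shift_test(rnorm(1000), rnorm(1000) + 1)
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$median_diff, 0.8)

  # 10-pair toy: brute-force null distribution over all 2^10 sign flips
  set.seed(3)
  before <- rnorm(10)
  after <- before + rnorm(10, 0.4, 0.7)
  d <- after - before
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 10))
  v_null <- as.matrix(signs) %*% r
  p_brute <- min(1, 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs)))
  expect_equal(paired_z_shift_test(before, after)$p_value, p_brute,
               tolerance = 1e-10)
})

test_that("observed fold changes are group mean differences in level order", {
  sheet <- toy_sheet(6, "B1", rep(c("control", "case"), each = 3))
  x <- toy_expr(c(1, 1, 2, 1, 3, 1, 5, 1, 6, 1, 7, 1), 2, 6)
  fc <- observed_log2_fc(x, sheet, levels = c("control", "case"))
  expect_equal(unname(fc), c(mean(x[1, 4:6]) - mean(x[1, 1:3]),
                             mean(x[2, 4:6]) - mean(x[2, 1:3])))
  xeq <- x
  xeq[, 4:6] <- x[, 1:3]         # identical group means
  expect_equal(unname(observed_log2_fc(xeq, sheet,
                                       levels = c("control", "case"))),
               c(0, 0))
  sheet$group <- c("a", "b", "c", "a", "b", "c")
  expect_error(observed_log2_fc(x, sheet), "2 levels")
})

test_that("fold-change agreement returns Spearman rho^2 and the OLS slope", {
  nominal <- rep(FC_LEVELS, each = 10)
  mask <- rep(TRUE, length(nominal))
  perfect <- fc_agreement(nominal, nominal, mask)
  expect_equal(perfect$spearman_r2, 1)
  expect_equal(perfect$slope, 1)
  att <- fc_agreement(nominal, 0.9 * nominal, mask)
  expect_equal(att$slope, 0.9)
  expect_equal(att$spearman_r2, 1)
  expect_error(fc_agreement(nominal, nominal, c(TRUE, TRUE, rep(FALSE, 118))),
               "3 DE")
})

test_that("slope homogeneity is an ANCOVA interaction F-test", {
  x <- seq(0, 5, length.out = 100)
  set.seed(8)
  y1 <- 1.0 * x + rnorm(100, 0, 0.05)
  y2 <- 0.5 * x + rnorm(100, 0, 0.05)
  expect_equal(slope_homogeneity_test(x, y1, x, y1), 1)
  expect_lt(slope_homogeneity_test(x, y1, x, y2), 1e-4)

  # 4-point toy: F equals the manual separate-vs-common-slope decomposition
  x1 <- c(0, 1, 2, 3); y1 <- c(0.1, 1.2, 1.9, 3.2)
  x2 <- c(0, 1, 2, 3); y2 <- c(0.2, 0.8, 1.1, 1.8)
  sse <- function(x, y) sum(lm(y ~ x)$residuals^2)
  sep <- sse(x1, y1) + sse(x2, y2)
  g <- rep(c(0, 1), each = 4)
  common <- sum(lm(c(y1, y2) ~ c(x1, x2) + g)$residuals^2)
  f_manual <- (common - sep) / (sep / 4)
  p_manual <- pf(f_manual, 1, 4, lower.tail = FALSE)
  expect_equal(slope_homogeneity_test(x1, y1, x2, y2), p_manual,
               tolerance = 1e-10)
  expect_error(slope_homogeneity_test(rep(1, 4), y1, x2, y2), "degenerate")
})

test_that("vectorized Welch tests match t.test and are calibrated under the null", {
  sim <- null_sim(n_genes = 50L, gamma_sd = 0, seed = 12L)
  res <- de_pvalues(sim$expr, sim$sheet, levels = c("control", "case"))
  grp <- sim$sheet$group
  for (g in c(1, 7, 23, 50)) {
    tt <- t.test(sim$expr[g, grp == "case"], sim$expr[g, grp == "control"])
    expect_equal(unname(res$p_value[g]), tt$p.value, tolerance = 1e-12)
    expect_equal(unname(res$statistic[g]), unname(tt$statistic),
                 tolerance = 1e-12)
  }
  # degenerate genes
  x <- toy_expr(rep(1, 10), 1, 10)
  sh <- toy_sheet(10, "B1", rep(c("a", "b"), 5))
  x[1, ] <- 3
  expect_equal(unname(de_pvalues(x, sh)$p_value), 1)
  x[1, sh$group == "b"] <- 9
  expect_lt(unname(de_pvalues(x, sh)$p_value), 1e-10)

  # type-I error calibration at alpha = 0.05 on a null simulation
  set.seed(2)
  G <- 10000L
  xn <- toy_expr(rnorm(G * 40), G, 40, gene_ids = sprintf("g%05d", 1:G),
                 sample_ids = sprintf("s%03d", 1:40))
  shn <- toy_sheet(40, "B1", rep(c("a", "b"), 20),
                   sample_ids = colnames(xn))
  p <- de_pvalues(xn, shn)$p_value
  expect_lt(abs(mean(p < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / G))
})

test_that("trapezoid ROC AUC equals the pairwise-concordance oracle", {
  scores <- c(5, 4, 3, 2, 1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  r <- roc_auc(scores, truth)
  expect_equal(r$auc, auc_oracle(scores, truth))
  expect_equal(roc_auc(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  # property: 100 random instances incl. ties, n <= 50
  for (case in 1:100) {
    set.seed(case)
    n <- sample(10:50, 1)
    s <- sample(round(rnorm(n), sample(0:2, 1)))
    t <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(t) || all(t)) t[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(s, t)$auc, auc_oracle(s, t), tolerance = 1e-12)
  }
})

test_that("the paired AUC comparison reproduces DeLong's test", {
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), c(60, 90))
  sa <- rnorm(150) + 2 * truth
  sb <- rnorm(150) + 0.5 * truth
  res <- auc_difference_test(sa, sb, truth)
  expect_equal(res$auc_a, auc_oracle(sa, truth))
  expect_lt(res$p_value, 0.05)
  expect_equal(auc_difference_test(sa, sa, truth)$p_value, 1)
  perfect <- as.numeric(truth)
  expect_lt(auc_difference_test(perfect, rnorm(150), truth)$p_value, 1e-6)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(truth, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(truth, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("MCC follows the closed form and the binary-correlation oracle", {
  expect_equal(mcc_from_counts(100, 0, 100, 0), 1)
  expect_equal(mcc_from_counts(0, 100, 0, 100), -1)
  expect_equal(mcc_from_counts(0, 0, 50, 50), 0)
  expect_error(mcc_from_counts(-1, 0, 0, 0), "negative")

  # confounded-design confusion matrix reconstructed from its marginal
  # rates (6518 calls, 5495/8800 false positives, 177/1200 false negatives)
  tp <- 6518 - 5495; fp <- 5495; fn <- 177; tn <- 8800 - 5495
  m <- mcc_from_counts(tp, fp, tn, fn)
  pred <- rep(c(1, 1, 0, 0), c(tp, fp, fn, tn))
  truth <- rep(c(1, 0, 1, 0), c(tp, fp, fn, tn))
  expect_equal(m, cor(pred, truth), tolerance = 1e-12)
})
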