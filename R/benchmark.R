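# End-to-end benchmark: generate a design, apply each adjustment method,
# score it with the full metric suite, and return a per-method report.

.apply_method <- function(method, expr, sheet, reference_group, seed,
                          sva_n_perm, combat_covariates = "group") {
  switch(method,
    unadjusted = expr,
    mean_center = mean_center(expr, sheet),
    ratio_g = ratio_g(expr, sheet, reference_group = reference_group),
    combat_p = combat(expr, sheet, covariates = combat_covariates,
                      parametric = TRUE)$expr,
    combat_n = combat(expr, sheet, covariates = combat_covariates,
                      parametric = FALSE)$expr,
    sva = sva_adjust(expr, sheet, primary = "group", n_perm = sva_n_perm,
                     seed = seed)$expr,
    stop("unknown method: ", method))
}

# TRUE when the group labels are completely determined by batch, in which
# case the group effect cannot be protected during adjustment
.group_confounded <- function(sheet) {
  bd <- stats::model.matrix(~ 0 + factor(sheet$batch))
  gd <- stats::model.matrix(~ factor(sheet$group))[, -1L, drop = FALSE]
  qr(cbind(bd, gd))$rank < ncol(bd) + ncol(gd)
}

#' Run the full batch-adjustment benchmark on one simulated design
#'
#' Generates the named design, applies every requested adjustment method,
#' and computes the applicable metrics: the PVCA batch-attributable variance
#' fraction; for the duplicate-run (VAS) design the median Fisher-z of
#' per-gene replicate correlations and of per-gene ICCs (computed after
#' per-gene standardization); for the case/control (AAS and confounded)
#' designs the fold-change Spearman r-squared and signal-detection slope
#' over the DE genes, the ROC-AUC of the Welch-test ranking against the
#' simulation truth, and the MCC of Benjamini-Hochberg calls at the given
#' FDR.  A method that cannot run on the design (e.g. ratio adjustment on
#' the confounded design, which has no reference samples in the case batch)
#' yields a row of NAs with the error recorded in the `note` column rather
#' than a crash.
#'
#' @param design `"aas"`, `"vas"` or `"confounded"`.
#' @param methods Methods to score, a subset of `"unadjusted"`,
#'   `"mean_center"`, `"ratio_g"`, `"combat_p"`, `"combat_n"`, `"sva"`.
#' @param spec A [batch_effect_spec()].
#' @param layout Optional batch layout for the AAS design (see
#'   [aas_layout()]); used for the batch-size sweep.
#' @param seed Integer seed.
#' @param n_genes Number of genes; defaults to the design's standard size.
#' @param fdr FDR level for significance calls (default 0.05).
#' @param pvca_threshold Variance threshold for PVCA (default 0.6).
#' @param sva_n_perm Permutations for the surrogate-variable null.
#' @return A `benchmark_report`: data.frame with one row per method and
#'   columns `method`, `pvca_batch_fraction`, `median_repl_z`,
#'   `median_icc_z`, `fc_r2`, `slope`, `auc`, `mcc`, `note`; the simulation
#'   and configuration are attached as attributes.
#' @export
run_benchmark <- function(design = c("aas", "vas", "confounded"),
                          methods = c("unadjusted", "mean_center", "ratio_g",
                                      "combat_p", "combat_n", "sva"),
                          spec = batch_effect_spec(), layout = NULL,
                          seed = 1L, n_genes = NULL, fdr = 0.05,
                          pvca_threshold = 0.6, sva_n_perm = 100L) {
  design <- match.arg(design)
  sim <- switch(design,
    vas = simulate_vas(spec, seed,
                       n_genes = if (is.null(n_genes)) 1000L else n_genes),
    aas = simulate_aas(layout = if (is.null(layout)) aas_layout() else layout,
                       spec = spec, seed = seed,
                       n_genes = if (is.null(n_genes)) 10000L else n_genes,
                       n_de = if (is.null(n_genes)) 1200L
                              else max(12L, round(0.12 * n_genes / 12) * 12L)),
    confounded = simulate_confounded(
      spec = spec, seed = seed,
      n_genes = if (is.null(n_genes)) 10000L else n_genes,
      n_de = if (is.null(n_genes)) 1200L
             else max(12L, round(0.12 * n_genes / 12) * 12L)))

  is_vas <- design == "vas"
  expr <- if (is_vas) sim$expr_batched else sim$expr
  sheet <- sim$sheet
  reference_group <- if (is_vas) "Profile1" else "control"
  group_levels <- if (is_vas) c("Profile1", "Profile2") else c("control", "case")
  combat_covariates <- "group"
  confounded_note <- ""
  if (.group_confounded(sheet)) {   # group cannot be protected (Table-S2 case)
    combat_covariates <- NULL
    confounded_note <- "group confounded with batch; adjusted without protecting it"
  }

  rows <- lapply(methods, function(method) {
    row <- data.frame(method = method, pvca_batch_fraction = NA_real_,
                      median_repl_z = NA_real_, median_icc_z = NA_real_,
                      fc_r2 = NA_real_, slope = NA_real_, auc = NA_real_,
                      mcc = NA_real_, note = "", stringsAsFactors = FALSE)
    adj <- tryCatch(
      .apply_method(method, expr, sheet, reference_group, seed, sva_n_perm,
                    combat_covariates),
      error = function(e) e)
    if (inherits(adj, "error")) {
      row$note <- conditionMessage(adj)
      return(row)
    }
    if (method %in% c("combat_p", "combat_n")) row$note <- confounded_note
    pv <- pvca(adj, sheet, factors = c("batch", "group"),
               include_interactions = TRUE, threshold = pvca_threshold)
    row$pvca_batch_fraction <- unname(pv$weighted_proportions["batch"])
    if (is_vas) {
      s_single <- suppressWarnings(standardize_genes(sim$expr_single))
      s_adj <- suppressWarnings(standardize_genes(adj))
      r <- replicate_gene_correlation(s_single, s_adj)
      row$median_repl_z <- stats::median(
        suppressWarnings(fisher_z(pmin(pmax(r, -1), 1))))
      comb <- cbind(sim$expr_single, adj)
      colnames(comb) <- c(paste0(colnames(sim$expr_single), "_r1"),
                          paste0(colnames(adj), "_r2"))
      isheet <- data.frame(
        sample_id = colnames(comb),
        batch = c(sim$sheet_single$batch, sheet$batch),
        group = rep(sheet$group, 2L),
        replicate_group = rep(c("r1", "r2"), each = ncol(adj)),
        subject = rep(sheet$sample_id, 2L),
        stringsAsFactors = FALSE)
      icc <- icc_per_gene(suppressWarnings(
        standardize_genes(comb, isheet, within = "replicate_group")),
        isheet, "replicate_group", "subject")
      row$median_icc_z <- stats::median(
        suppressWarnings(fisher_z(pmin(pmax(icc, -1), 1))))
    } else {
      truth <- sim$truth
      obs <- observed_log2_fc(adj, sheet, levels = group_levels)
      fa <- fc_agreement(truth$nominal_log2_fc, obs, truth$is_de)
      row$fc_r2 <- fa$spearman_r2
      row$slope <- fa$slope
      test <- de_pvalues(adj, sheet, levels = group_levels)
      row$auc <- roc_auc(de_scores(test), truth$is_de)$auc
      calls <- de_calls(test$p_value, fdr)
      row$mcc <- mcc_from_counts(tp = sum(calls & truth$is_de),
                                 fp = sum(calls & !truth$is_de),
                                 tn = sum(!calls & !truth$is_de),
                                 fn = sum(!calls & truth$is_de))
    }
    row
  })
  report <- do.call(rbind, rows)
  structure(report, class = c("benchmark_report", "data.frame"),
            design = design, seed = seed, spec = spec, sim = sim, fdr = fdr)
}

#' @export
print.benchmark_report <- function(x, digits = 3L, ...) {
  cat("Batch-adjustment benchmark --", attr(x, "design"), "design, seed",
      attr(x, "seed"), "\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], signif, digits)
  keep <- c("method", names(y)[num][colSums(!is.na(y[num])) > 0], "note")
  print.data.frame(y[, unique(keep), drop = FALSE], row.names = FALSE)
  invisible(x)
}
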