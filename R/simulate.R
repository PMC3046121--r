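# Simulation of log2 expression data under the location/scale (L/S) batch
# model:
#
#   Y_ijg = alpha_g + X_j * beta_g + gamma_ig + delta_ig * eps_jg,
#   eps_jg ~ N(0, sigma_g^2)
#
# alpha_g  per-gene baseline mean (log2 units)
# beta_g   per-gene group effect = nominal log2 fold change
# gamma_ig additive batch effect of batch i for gene g
# delta_ig multiplicative batch effect (scale factor on the noise)
#
# gamma_ig are drawn Normal(0, gamma_sd^2); delta_ig^2 are drawn from an
# inverse-gamma distribution.  All randomness flows from one master seed,
# split deterministically into per-stage streams so that adding a stage
# never perturbs the draws of another.

#' The twelve nominal log2 fold-change levels of the accuracy design
#'
#' Raw-scale fold changes -3, -2.5, -2, -1.5, -1.2, -1.1 and their inverses,
#' on the log2 scale.
#' @export
FC_LEVELS <- c(-1.58, -1.32, -1, -0.58, -0.26, -0.14,
               0.14, 0.26, 0.58, 1, 1.32, 1.58)

# Shipped batch-effect defaults.  The distribution families are part of the
# model; the parameters were calibrated once against the variance-assessment
# design's batch-attributable variance share (~30% of overall variation) and
# frozen.  delta2 ~ InvGamma(8, 8.05) has mean 1.15, sd ~ 0.47.
GAMMA_SD_DEFAULT <- 0.55
DELTA_SHAPE_DEFAULT <- 8
DELTA_SCALE_DEFAULT <- 8.05

# Detection margin used to set per-gene noise: sigma_g is chosen so that a
# two-sample test on clean data sees the group effect at about z* standard
# errors -- detectably DE, but with small fold changes near the edge.
SIGMA_ZSTAR <- 3.3

#' Batch-effect magnitude specification
#'
#' Describes the distributions from which per-batch-per-gene effects are
#' drawn: additive effects `gamma_ig ~ Normal(0, gamma_sd^2)` (log2 units)
#' and squared multiplicative effects
#' `delta_ig^2 ~ InverseGamma(delta_shape, delta_scale)` (so
#' `E[delta^2] = delta_scale / (delta_shape - 1)`).  `delta_fixed`, if given,
#' pins every `delta_ig` to that constant instead (useful for the
#' no-scale-effect limit).
#'
#' @param gamma_sd Standard deviation of the additive batch effects; >= 0.
#' @param delta_shape Inverse-gamma shape; must exceed 2 (finite variance).
#' @param delta_scale Inverse-gamma scale; > 0.
#' @param delta_fixed Optional positive constant overriding the delta draw.
#' @return An object of class `batch_effect_spec`.
#' @export
batch_effect_spec <- function(gamma_sd = GAMMA_SD_DEFAULT,
                              delta_shape = DELTA_SHAPE_DEFAULT,
                              delta_scale = DELTA_SCALE_DEFAULT,
                              delta_fixed = NULL) {
  stopifnot(gamma_sd >= 0, delta_shape > 2, delta_scale > 0)
  if (!is.null(delta_fixed)) stopifnot(delta_fixed > 0)
  mean_delta2 <- delta_scale / (delta_shape - 1)
  if (is.null(delta_fixed) && (mean_delta2 <= 0.25 || mean_delta2 >= 4))
    stop("E[delta^2] = ", signif(mean_delta2, 3),
         " is outside the sane range (0.25, 4)")
  structure(list(gamma_sd = gamma_sd, delta_shape = delta_shape,
                 delta_scale = delta_scale, delta_fixed = delta_fixed),
            class = "batch_effect_spec")
}

# Deterministic split of one master seed into named stage streams.
# Multiplicative hash of the stage name folded into [0, 2^31 - 2].
.stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Draw the per-batch-per-gene effect matrices (B x G each) for one design.
.draw_batch_effects <- function(spec, batch_labels, n_genes, seed) {
  B <- length(batch_labels)
  set.seed(.stage_seed(seed, "gamma"))
  gamma <- matrix(stats::rnorm(B * n_genes, 0, spec$gamma_sd), nrow = B,
                  dimnames = list(batch_labels, NULL))
  set.seed(.stage_seed(seed, "delta"))
  if (is.null(spec$delta_fixed)) {
    delta2 <- matrix(1 / stats::rgamma(B * n_genes, shape = spec$delta_shape,
                                       rate = spec$delta_scale),
                     nrow = B, dimnames = list(batch_labels, NULL))
  } else {
    delta2 <- matrix(spec$delta_fixed^2, nrow = B, ncol = n_genes,
                     dimnames = list(batch_labels, NULL))
  }
  list(gamma = gamma, delta2 = delta2)
}

#' L/S model parameter bundle
#'
#' @param alpha Per-gene baseline means (length G).
#' @param beta Per-gene group effects, i.e. nominal log2 fold changes
#'   (length G).
#' @param sigma Per-gene error standard deviations (length G, >= 0).
#' @param gamma B x G matrix of additive batch effects; rownames are batch
#'   labels.
#' @param delta2 B x G matrix of squared multiplicative batch effects
#'   (> 0); rownames must match `gamma`.
#' @param treatment_level Group label whose samples receive `beta` (the
#'   design indicator X is 1 for this level, 0 otherwise).
#' @return An object of class `ls_model_params`.
#' @export
ls_model_params <- function(alpha, beta, sigma, gamma, delta2,
                            treatment_level) {
  G <- length(alpha)
  stopifnot(length(beta) == G, length(sigma) == G, all(sigma >= 0),
            is.matrix(gamma), is.matrix(delta2),
            ncol(gamma) == G, ncol(delta2) == G,
            nrow(gamma) == nrow(delta2), all(delta2 > 0),
            !is.null(rownames(gamma)),
            identical(rownames(gamma), rownames(delta2)))
  structure(list(alpha = alpha, beta = beta, sigma = sigma, gamma = gamma,
                 delta2 = delta2, treatment_level = treatment_level),
            class = "ls_model_params")
}

#' Draw an expression matrix from the L/S model
#'
#' Generates `Y_ijg = alpha_g + X_j beta_g + gamma_ig + delta_ig eps_jg`
#' with `eps_jg ~ N(0, sigma_g^2)`, where sample j belongs to the batch and
#' group recorded in `sheet`.  Identical seeds give identical matrices.
#'
#' @param params An [ls_model_params()] bundle.
#' @param sheet Sample sheet giving each sample's batch and group; every
#'   batch label must have a row in `params$gamma`.
#' @param seed Integer seed.
#' @return Expression matrix (G x N) with gene ids `g0001, ...` and the
#'   sheet's sample ids.
#' @export
sample_ls_model <- function(params, sheet, seed) {
  stopifnot(inherits(params, "ls_model_params"))
  validate_sample_sheet(sheet)
  G <- length(params$alpha)
  N <- nrow(sheet)
  batch <- as.character(sheet$batch)
  unknown <- setdiff(unique(batch), rownames(params$gamma))
  if (length(unknown))
    stop("batch label(s) not in model parameters: ",
         paste(unknown, collapse = ", "))
  x <- as.numeric(as.character(sheet$group) == params$treatment_level)
  bi <- match(batch, rownames(params$gamma))
  set.seed(.stage_seed(seed, "eps"))
  eps <- matrix(stats::rnorm(G * N), nrow = G) * params$sigma
  y <- params$alpha + outer(params$beta, x) +
    t(params$gamma[bi, , drop = FALSE]) +
    t(sqrt(params$delta2[bi, , drop = FALSE])) * eps
  dimnames(y) <- list(sprintf("g%04d", seq_len(G)), sheet$sample_id)
  validate_expression_matrix(y)
  y
}

# Noise rule shared by the designs: sigma_g for a DE gene puts the clean-data
# two-sample z-statistic at ~SIGMA_ZSTAR; null genes resample from the DE
# genes' sigma distribution.
.sigma_rule <- function(beta, n1, n2, seed) {
  de <- beta != 0
  sigma <- numeric(length(beta))
  sigma[de] <- abs(beta[de]) * sqrt(n1 * n2 / (n1 + n2)) / SIGMA_ZSTAR
  if (any(!de)) {
    set.seed(.stage_seed(seed, "sigma_null"))
    sigma[!de] <- sample(sigma[de], sum(!de), replace = TRUE)
  }
  sigma
}

.truth_frame <- function(gene_ids, beta, gamma, delta2) {
  structure(
    data.frame(gene_id = gene_ids, is_de = beta != 0,
               nominal_log2_fc = beta, stringsAsFactors = FALSE),
    gamma = gamma, delta2 = delta2)
}

#' Simulate the variation-assessment (VAS) design
#'
#' 100 samples (65 assigned to Profile1, 35 to Profile2) measured on 1000
#' genes, all differentially expressed between the profiles with nominal
#' log2 fold changes cycling over the twelve levels in [FC_LEVELS].  The
#' whole study is generated twice as technical replicates over the same
#' alpha/beta/sigma and sample assignments: replicate 1 as if run in a
#' single batch (no batch effects), replicate 2 as if run in two batches of
#' 50 with batch effects drawn from `spec`.  Batch assignment in replicate 2
#' is alternated within profile, so profiles are nearly balanced across the
#' two batches.
#'
#' @param spec A [batch_effect_spec()].
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 1000).
#' @return List of class `vas_sim` with elements `expr_single` (replicate 1,
#'   one batch), `expr_batched` (replicate 2, two batches), `sheet` (batch
#'   labels of replicate 2), `sheet_single`, `truth` and `params`.
#' @export
simulate_vas <- function(spec = batch_effect_spec(), seed = 1L,
                         n_genes = 1000L) {
  stopifnot(inherits(spec, "batch_effect_spec"))
  n1 <- 65L; n2 <- 35L
  group <- c(rep("Profile1", n1), rep("Profile2", n2))
  sample_id <- sprintf("s%03d", seq_len(n1 + n2))
  # alternate within profile across the two batches of replicate 2
  batch2 <- character(n1 + n2)
  batch2[group == "Profile1"] <- rep_len(c("B1", "B2"), n1)
  batch2[group == "Profile2"] <- rep_len(c("B1", "B2"), n2)
  sheet <- data.frame(sample_id = sample_id, batch = batch2, group = group,
                      stringsAsFactors = FALSE)
  sheet_single <- transform(sheet, batch = "B0")

  beta <- rep_len(FC_LEVELS, n_genes)
  set.seed(.stage_seed(seed, "alpha"))
  alpha <- stats::rnorm(n_genes, mean = 7, sd = 2)
  sigma <- .sigma_rule(beta, n1, n2, seed)

  eff <- .draw_batch_effects(spec, c("B1", "B2"), n_genes, seed)
  params1 <- ls_model_params(alpha, beta, sigma,
                             gamma = matrix(0, 1, n_genes,
                                            dimnames = list("B0", NULL)),
                             delta2 = matrix(1, 1, n_genes,
                                             dimnames = list("B0", NULL)),
                             treatment_level = "Profile2")
  params2 <- ls_model_params(alpha, beta, sigma, eff$gamma, eff$delta2,
                             treatment_level = "Profile2")
  expr_single <- sample_ls_model(params1, sheet_single,
                                 .stage_seed(seed, "rep1"))
  expr_batched <- sample_ls_model(params2, sheet,
                                  .stage_seed(seed, "rep2"))
  truth <- .truth_frame(rownames(expr_single), beta, eff$gamma, eff$delta2)
  structure(list(expr_single = expr_single, expr_batched = expr_batched,
                 sheet = sheet, sheet_single = sheet_single, truth = truth,
                 params = params2, spec = spec, seed = seed),
            class = "vas_sim")
}

#' Default accuracy-design batch layout
#'
#' Splits 100 cases and 100 controls into batches of `batch_size` samples.
#' The first two batches are imbalanced mirror images (25% cases vs 75%
#' cases) to exercise the reverse case/control-ratio scenario; the remaining
#' batches are balanced.
#'
#' @param batch_size Samples per batch; must divide 200 and give at least two
#'   batches (20, 40 or 100 in the batch-size sweep).
#' @return data.frame with columns `batch`, `n_case`, `n_control`.
#' @export
aas_layout <- function(batch_size = 40L) {
  stopifnot(200L %% batch_size == 0L, batch_size >= 4L, batch_size <= 100L)
  B <- 200L %/% batch_size
  n_case <- rep(batch_size %/% 2L, B)
  n_case[1L] <- batch_size %/% 4L
  n_case[2L] <- batch_size - batch_size %/% 4L
  data.frame(batch = sprintf("B%d", seq_len(B)),
             n_case = n_case, n_control = batch_size - n_case,
             stringsAsFactors = FALSE)
}

#' Simulate the accuracy-assessment (AAS) design
#'
#' 10,000 genes in 100 cases and 100 controls; exactly 1,200 genes are
#' differentially expressed, 100 at each of the twelve nominal log2
#' fold-change levels `+/- {0.14, 0.26, 0.58, 1, 1.32, 1.58}` (cases relative
#' to controls).  Batch effects are drawn from `spec` over the batches in
#' `layout`.
#'
#' @param layout Batch layout data.frame with columns `batch`, `n_case`,
#'   `n_control` summing to the design totals (see [aas_layout()]).
#' @param spec A [batch_effect_spec()].
#' @param seed Integer seed.
#' @param n_genes,n_de,n_case,n_control Design sizes; defaults are the
#'   standard design (10,000 genes, 1,200 DE, 100 + 100 samples).
#' @return List of class `aas_sim` with elements `expr`, `sheet`, `truth`,
#'   `params`.
#' @export
simulate_aas <- function(layout = aas_layout(), spec = batch_effect_spec(),
                         seed = 1L, n_genes = 10000L, n_de = 1200L,
                         n_case = 100L, n_control = 100L) {
  stopifnot(inherits(spec, "batch_effect_spec"),
            is.data.frame(layout),
            all(c("batch", "n_case", "n_control") %in% names(layout)),
            n_de %% length(FC_LEVELS) == 0L, n_de < n_genes)
  if (sum(layout$n_case) != n_case || sum(layout$n_control) != n_control)
    stop("batch layout must sum to ", n_case, " cases and ",
         n_control, " controls")

  # sample sheet: cases then controls within each batch
  rows <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    data.frame(batch = layout$batch[i],
               group = c(rep("case", layout$n_case[i]),
                         rep("control", layout$n_control[i])),
               stringsAsFactors = FALSE)
  }))
  rows$sample_id <- sprintf("%s_%03d", substr(rows$group, 1, 4),
                            stats::ave(seq_len(nrow(rows)), rows$group,
                                       FUN = seq_along))
  sheet <- rows[, c("sample_id", "batch", "group")]
  rownames(sheet) <- NULL

  beta <- c(rep(FC_LEVELS, each = n_de %/% length(FC_LEVELS)),
            rep(0, n_genes - n_de))
  set.seed(.stage_seed(seed, "alpha"))
  alpha <- stats::rnorm(n_genes, mean = 7, sd = 2)
  sigma <- .sigma_rule(beta, n_case, n_control, seed)
  eff <- .draw_batch_effects(spec, layout$batch, n_genes, seed)
  params <- ls_model_params(alpha, beta, sigma, eff$gamma, eff$delta2,
                            treatment_level = "case")
  expr <- sample_ls_model(params, sheet, .stage_seed(seed, "aas"))
  truth <- .truth_frame(rownames(expr), beta, eff$gamma, eff$delta2)
  structure(list(expr = expr, sheet = sheet, truth = truth, params = params,
                 spec = spec, seed = seed),
            class = "aas_sim")
}

#' Simulate the fully confounded design
#'
#' The accuracy design re-configured so that batch coincides with case
#' status: all 100 cases in batch B1 and all 100 controls in batch B2.
#' Biological and batch variation are then inseparable; a ratio-to-reference
#' adjustment cannot even be computed (no reference samples in the case
#' batch) and adjustment methods that are blind to the group label remove
#' the case/control signal together with the batch effect.
#'
#' @inheritParams simulate_aas
#' @return List of class `aas_sim` (same structure as [simulate_aas()]).
#' @export
simulate_confounded <- function(spec = batch_effect_spec(), seed = 1L,
                                n_genes = 10000L, n_de = 1200L) {
  layout <- data.frame(batch = c("B1", "B2"),
                       n_case = c(100L, 0L), n_control = c(0L, 100L),
                       stringsAsFactors = FALSE)
  simulate_aas(layout = layout, spec = spec, seed = seed,
               n_genes = n_genes, n_de = n_de)
}

#' @export
print.vas_sim <- function(x, ...) {
  cat("Variation-assessment simulation:",
      nrow(x$expr_single), "genes x", ncol(x$expr_single),
      "samples (duplicate run, 1 vs 2 batches)\n")
  cat("  groups:", paste(names(table(x$sheet$group)),
                         table(x$sheet$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.aas_sim <- function(x, ...) {
  cat("Accuracy-assessment simulation:",
      nrow(x$expr), "genes x", ncol(x$expr), "samples;",
      sum(x$truth$is_de), "DE genes over",
      length(unique(x$truth$nominal_log2_fc[x$truth$is_de])),
      "log2 fold-change levels\n")
  cat("  batches:", paste(names(table(x$sheet$batch)),
                          table(x$sheet$batch), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation to TSV files
#'
#' Emits the standard expression TSV(s), sample sheet TSV and a truth TSV
#' (`gene_id`, `is_de`, `nominal_log2_fc`) into `dir`.
#'
#' @param sim A `vas_sim` or `aas_sim` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (inherits(sim, "vas_sim")) {
    files <- c(file.path(dir, "expr_single.tsv"),
               file.path(dir, "expr_batched.tsv"))
    write_expression_tsv(sim$expr_single, files[1])
    write_expression_tsv(sim$expr_batched, files[2])
  } else {
    files <- file.path(dir, "expr.tsv")
    write_expression_tsv(sim$expr, files)
  }
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(sim$sheet, sheet_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, sheet_path, truth_path))
}
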