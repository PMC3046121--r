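# Metric suite: precision (probe standardization, replicate correlation,
# ICC, Fisher z), accuracy (fold-change agreement, signal-detection slope,
# slope homogeneity), and overall performance (per-gene Welch tests,
# ROC-AUC, DeLong comparison, Matthews correlation coefficient).

.row_center_scale <- function(x, floor = 1e-8) {
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  if (any(s < floor)) {
    warning(sum(s < floor), " gene(s) with (near-)zero variance; ",
            "s.d. floored at ", floor)
    s <- pmax(s, floor)
  }
  (x - m) / s
}

#' Standardize each gene to mean 0, s.d. 1
#'
#' Microarray data carry a large probe effect: gene baselines dominate the
#' sample-to-sample covariance and inflate correlations between *any* two
#' samples, replicates or not.  Standardizing each gene removes it.  When
#' `within` names a sample-sheet column (e.g. a replicate-group label), the
#' standardization is done separately inside each stratum.
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet; required when `within` is given.
#' @param within Optional sheet column defining standardization strata.
#' @return Matrix of the same shape with per-gene (per-stratum) mean 0 and
#'   s.d. 1.
#' @export
standardize_genes <- function(expr, sheet = NULL, within = NULL) {
  validate_expression_matrix(expr)
  if (is.null(within)) {
    if (ncol(expr) < 3L) stop("need >= 3 samples to standardize")
    return(.row_center_scale(expr))
  }
  strata <- .sheet_col(expr, sheet, within)
  out <- expr
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 3L)
      stop("stratum '", s, "' has fewer than 3 samples")
    out[, idx] <- .row_center_scale(expr[, idx, drop = FALSE])
  }
  out
}

#' Per-gene Pearson correlation between paired replicate matrices
#'
#' @param expr_a,expr_b Expression matrices over identical genes and samples
#'   (technical replicates of the same study).
#' @return Named vector: for each gene, the Pearson correlation of its
#'   values across the paired samples.
#' @export
replicate_gene_correlation <- function(expr_a, expr_b) {
  validate_expression_matrix(expr_a)
  validate_expression_matrix(expr_b)
  if (!identical(dimnames(expr_a), dimnames(expr_b)))
    stop("matrices must share identical gene and sample ids")
  n <- ncol(expr_a)
  if (n < 3L) stop("need >= 3 paired samples")
  za <- .row_center_scale(expr_a)
  zb <- .row_center_scale(expr_b)
  stats::setNames(rowSums(za * zb) / (n - 1L), rownames(expr_a))
}

#' One-way random-effects intraclass correlation per gene
#'
#' For a complete design in which every subject is measured once in every
#' replicate group, computes per gene
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way
#' between-subject / within-subject mean squares, with k replicate groups.
#'
#' @param expr Expression matrix over all replicate measurements.
#' @param sheet Sample sheet covering the matrix samples.
#' @param replicate_col Sheet column labelling the replicate group.
#' @param subject_col Sheet column labelling the subject.
#' @return Named per-gene ICC vector (can be slightly negative when subject
#'   means agree no better than chance; values are not clipped).
#' @export
icc_per_gene <- function(expr, sheet, replicate_col = "replicate_group",
                         subject_col = "subject") {
  validate_expression_matrix(expr)
  repl <- .sheet_col(expr, sheet, replicate_col)
  subj <- .sheet_col(expr, sheet, subject_col)
  tab <- table(subj, repl)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop("incomplete design; missing/extra cells for subject x replicate: ",
         paste(rownames(tab)[bad[, 1L]], colnames(tab)[bad[, 2L]],
               sep = "/", collapse = ", "))
  }
  k <- ncol(tab)
  n <- nrow(tab)
  if (k < 2L) stop("need >= 2 replicate groups")
  subj_f <- factor(subj)
  ind <- stats::model.matrix(~ 0 + subj_f)            # N x n indicator
  subj_means <- (expr %*% ind) / k                    # G x n
  grand <- rowMeans(expr)
  msb <- k * rowSums((subj_means - grand)^2) / (n - 1L)
  msw <- rowSums((expr - subj_means[, as.integer(subj_f), drop = FALSE])^2) /
    (n * (k - 1L))
  stats::setNames((msb - msw) / (msb + (k - 1L) * msw), rownames(expr))
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; values at exactly +/- 1
#' are clipped to +/- (1 - 1e-12) with a warning.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @return z score(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warning("correlation(s) at +/-1 clipped before the z-transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' Paired shift test on Fisher-z vectors
#'
#' Wilcoxon signed-rank test of whether a correction method shifted the
#' per-gene z-score distribution, paired by gene.
#'
#' @param z_before,z_after Equal-length paired z vectors.
#' @return List with `median_diff` (median of after - before) and `p_value`.
#' @export
paired_z_shift_test <- function(z_before, z_after) {
  stopifnot(length(z_before) == length(z_after))
  d <- z_after - z_before
  if (all(d == 0)) return(list(median_diff = 0, p_value = 1))
  p <- suppressWarnings(
    stats::wilcox.test(z_after, z_before, paired = TRUE))$p.value
  list(median_diff = stats::median(d), p_value = p)
}

#' Observed per-gene log2 fold change between two groups
#'
#' @param expr Expression matrix (log2).
#' @param sheet Sample sheet.
#' @param group_col Sheet column with exactly two levels.
#' @param levels Optional length-2 character vector fixing the order; the
#'   fold change is `mean(levels[2]) - mean(levels[1])`.  Defaults to the
#'   column's factor levels (or order of first appearance).
#' @return Named per-gene log2 fold-change vector.
#' @export
observed_log2_fc <- function(expr, sheet, group_col = "group",
                             levels = NULL) {
  validate_expression_matrix(expr)
  g <- .sheet_col(expr, sheet, group_col)
  if (is.null(levels)) {
    levels <- if (is.factor(sheet[[group_col]])) base::levels(sheet[[group_col]])
              else unique(g)
  }
  if (length(levels) != 2L || !setequal(unique(g), levels))
    stop("group column must have exactly the 2 levels ",
         paste(levels, collapse = ", "))
  m2 <- rowMeans(expr[, g == levels[2L], drop = FALSE])
  m1 <- rowMeans(expr[, g == levels[1L], drop = FALSE])
  stats::setNames(m2 - m1, rownames(expr))
}

#' Fold-change agreement: Spearman r-squared and signal-detection slope
#'
#' Over the truly differentially expressed genes only, computes the squared
#' Spearman correlation between nominal and observed log2 fold changes, and
#' the ordinary-least-squares slope of observed regressed on nominal (a
#' slope of 1 means fold changes are recovered without attenuation or
#' inflation).
#'
#' @param nominal,observed Per-gene log2 fold-change vectors.
#' @param de_mask Logical per-gene vector flagging the DE genes.
#' @return List with `spearman_r2` and `slope`.
#' @export
fc_agreement <- function(nominal, observed, de_mask) {
  stopifnot(length(nominal) == length(observed),
            length(de_mask) == length(nominal))
  x <- nominal[de_mask]
  y <- observed[de_mask]
  if (length(x) < 3L) stop("fewer than 3 DE genes")
  rho <- stats::cor(x, y, method = "spearman")
  slope <- stats::cov(x, y) / stats::var(x)
  list(spearman_r2 = rho^2, slope = slope)
}

#' Test for homogeneity of two regression slopes
#'
#' ANCOVA interaction F-test: fits the pooled regression with a group-by-x
#' interaction and reports the p-value of the interaction term.
#'
#' @param x1,y1 Paired vectors for dataset 1.
#' @param x2,y2 Paired vectors for dataset 2.
#' @return Interaction p-value.
#' @export
slope_homogeneity_test <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 3L, length(x2) >= 3L)
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("degenerate predictor (zero variance)")
  dat <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = factor(rep(c("a", "b"), c(length(x1), length(x2)))))
  a <- stats::anova(stats::lm(y ~ x * g, data = dat))
  p <- a["x:g", "Pr(>F)"]
  if (is.na(p)) p <- 1            # exactly collinear interaction (F = 0)
  p
}

#' Per-gene Welch two-sample t-test p-values
#'
#' Vectorized Welch (unequal-variance) t-tests of the two `group_col`
#' levels for every gene.  Genes with zero variance in both groups and no
#' mean difference get p = 1.
#'
#' @inheritParams observed_log2_fc
#' @return List with per-gene vectors `p_value`, `statistic`, `df`.
#' @export
de_pvalues <- function(expr, sheet, group_col = "group", levels = NULL) {
  validate_expression_matrix(expr)
  g <- .sheet_col(expr, sheet, group_col)
  if (is.null(levels)) {
    levels <- if (is.factor(sheet[[group_col]])) base::levels(sheet[[group_col]])
              else unique(g)
  }
  if (length(levels) != 2L || !setequal(unique(g), levels))
    stop("group column must have exactly 2 levels")
  i1 <- g == levels[1L]; i2 <- g == levels[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  x1 <- expr[, i1, drop = FALSE]; x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  df[!is.finite(df)] <- 1        # placeholder; zero-variance genes reset below
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  if (any(zero)) {            # constant within both groups
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
    tstat[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m2 - m1)[zero])
    df[zero] <- n1 + n2 - 2L
  }
  list(p_value = stats::setNames(p, rownames(expr)),
       statistic = stats::setNames(tstat, rownames(expr)),
       df = stats::setNames(df, rownames(expr)))
}

#' Benjamini-Hochberg significance calls
#'
#' @param p Per-gene p-values.
#' @param fdr False-discovery-rate level (default 0.05).
#' @return Logical vector of calls.
#' @export
de_calls <- function(p, fdr = 0.05) {
  stats::p.adjust(p, method = "BH") <= fdr
}

#' Ranking statistic for ROC analysis
#'
#' `-log10` p-value with ties broken by the magnitude of the t statistic.
#'
#' @param test Result of [de_pvalues()].
#' @return Per-gene score vector (larger = stronger DE evidence).
#' @export
de_scores <- function(test) {
  -log10(pmax(test$p_value, .Machine$double.xmin)) +
    1e-9 * abs(test$statistic) / (1 + abs(test$statistic))
}

#' ROC curve and area under the curve
#'
#' Sweeps a threshold over the scores (ties grouped), accumulating the true
#' and false positive rates, and integrates by the trapezoid rule.  The
#' result equals the Mann-Whitney pairwise concordance probability with
#' ties counted 1/2.
#'
#' @param scores Per-gene ranking statistic (larger = called positive first).
#' @param truth Logical per-gene vector of true DE flags.
#' @return List with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  # collapse tied scores into single thresholds
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(t)[last]
  fp <- cumsum(!t)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# placement values for the DeLong machinery: for each positive, the
# fraction of negatives it beats (ties 1/2), and vice versa
.delong_placements <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for a difference in AUC
#'
#' Compares the AUCs of two ranking statistics computed on the same genes
#' against the same truth, using the DeLong structural-components
#' (placement-value) variance estimate for paired curves.
#'
#' @param scores_a,scores_b Per-gene ranking statistics.
#' @param truth Logical per-gene DE flags (shared).
#' @return List with `auc_a`, `auc_b`, `z` and `p_value` (two-sided).
#' @export
auc_difference_test <- function(scores_a, scores_b, truth) {
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  truth <- as.logical(truth)
  if (!sum(truth) || !sum(!truth)) stop("truth must contain both classes")
  pa <- .delong_placements(scores_a, truth)
  pb <- .delong_placements(scores_b, truth)
  m <- sum(truth); n <- sum(!truth)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p)
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as
#' 0 when any marginal is zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion-matrix counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("negative confusion-matrix count")
  if (sum(counts) == 0) stop("empty confusion matrix")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}
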