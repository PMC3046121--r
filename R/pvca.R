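# Principal variance component analysis: PCA on gene-standardized data in
# sample space, then a random-effects variance decomposition of each
# retained principal component, eigenvalue-weighted into overall factor
# proportions.

#' Random-effects variance components of one response vector
#'
#' Fits a mixed linear model with a random intercept for every factor in
#' `factor_assignments` (crossed, REML via lme4) and returns the estimated
#' variance component per factor plus the residual.  Components are clipped
#' at zero.  A factor with a single level contributes a zero component with
#' a warning; a constant response returns all-zero components.
#'
#' @param y Numeric response vector (one value per sample).
#' @param factor_assignments Named list of per-sample labels, one element
#'   per factor (interaction factors may be supplied pre-combined, e.g.
#'   `paste(batch, group)`).
#' @return Named numeric vector of variance components, with a final
#'   `"resid"` element; entries sum to approximately `var(y)`.
#' @export
estimate_variance_components <- function(y, factor_assignments) {
  if (!all(is.finite(y))) stop("non-finite values in response")
  stopifnot(is.list(factor_assignments), length(factor_assignments) >= 1L,
            !is.null(names(factor_assignments)))
  n <- length(y)
  lens <- vapply(factor_assignments, length, integer(1L))
  if (any(lens != n)) stop("factor assignment length mismatch")
  comps <- stats::setNames(numeric(length(factor_assignments)),
                           names(factor_assignments))
  if (stats::var(y) < 1e-12) return(c(comps, resid = 0))

  active <- character()
  for (f in names(factor_assignments)) {
    if (length(unique(factor_assignments[[f]])) < 2L) {
      warning("factor '", f, "' has a single level; component set to 0")
    } else {
      active <- c(active, f)
    }
  }
  if (!length(active)) return(c(comps, resid = stats::var(y)))

  dat <- data.frame(.y = y)
  safe <- make.names(active)
  for (i in seq_along(active))
    dat[[safe[i]]] <- factor(factor_assignments[[active[i]]])
  form <- stats::as.formula(paste(
    ".y ~", paste(sprintf("(1 | %s)", safe), collapse = " + ")))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  for (i in seq_along(active))
    comps[active[i]] <- max(vc$vcov[vc$grp == safe[i]], 0)
  resid <- max(vc$vcov[vc$grp == "Residual"], 0)
  c(comps, resid = resid)
}

#' Principal variance component analysis
#'
#' Attributes the overall variance of an expression matrix to named sample
#' factors.  Genes are standardized (mean 0, s.d. 1), a PCA is run on the
#' sample-by-sample covariance, the smallest set of leading components whose
#' cumulative explained variance reaches `threshold` is retained, each
#' retained component is decomposed into per-factor variance components by a
#' random-effects fit, and the per-component proportions are averaged with
#' eigenvalue weights (normalized over the retained set).
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet containing the factor columns.
#' @param factors Character vector of sheet columns to attribute variance to.
#' @param include_interactions Also include all pairwise interactions of
#'   `factors` (labelled `"a:b"`).
#' @param threshold Fraction of overall variance the retained components
#'   must reach (default 0.6).
#' @return Object of class `pvca_result`: list with `weighted_proportions`
#'   (named, includes `"resid"`, sums to 1), `retained_pc_count`,
#'   `eigenvalues` (retained), and `per_pc_components` (matrix, factors x
#'   retained PCs).
#' @export
pvca <- function(expr, sheet, factors = c("batch", "group"),
                 include_interactions = TRUE, threshold = 0.6) {
  validate_expression_matrix(expr)
  stopifnot(threshold > 0, threshold <= 1)
  al <- align_samples(expr, sheet, strict = TRUE)
  expr <- al$expr; sheet <- al$sheet
  miss <- setdiff(factors, names(sheet))
  if (length(miss)) stop("factor(s) not in sheet: ", paste(miss, collapse = ", "))
  N <- ncol(expr)

  # continuous covariates (age, pH, ...) enter as random factors via
  # tertile bins
  as_factor_labels <- function(v) {
    if (is.numeric(v)) {
      br <- unique(stats::quantile(v, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE))
      if (length(br) < 3L) return(as.character(v))
      as.character(cut(v, breaks = br, include.lowest = TRUE,
                       labels = paste0("T", seq_len(length(br) - 1L))))
    } else as.character(v)
  }
  assignments <- lapply(factors, function(f) as_factor_labels(sheet[[f]]))
  names(assignments) <- factors
  if (include_interactions && length(factors) > 1L) {
    pairs <- utils::combn(factors, 2L, simplify = FALSE)
    for (p in pairs)
      assignments[[paste(p, collapse = ":")]] <-
        paste(assignments[[p[1L]]], assignments[[p[2L]]], sep = ":")
  }
  if (N <= max(vapply(assignments, function(a) length(unique(a)), integer(1L))))
    stop("more factor levels than samples")

  sds <- apply(expr, 1L, stats::sd)
  keep <- sds > 1e-10
  Z <- (expr[keep, , drop = FALSE] - rowMeans(expr[keep, , drop = FALSE])) /
    sds[keep]
  S <- crossprod(Z) / (nrow(Z) - 1L)
  ei <- eigen(S, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= threshold)[1L]

  per_pc <- matrix(0, length(assignments) + 1L, m,
                   dimnames = list(c(names(assignments), "resid"),
                                   paste0("PC", seq_len(m))))
  for (k in seq_len(m)) {
    vc <- estimate_variance_components(ei$vectors[, k], assignments)
    per_pc[, k] <- vc / sum(vc)       # standardized within the component
  }
  w <- ev[seq_len(m)] / sum(ev[seq_len(m)])
  weighted <- as.numeric(per_pc %*% w)
  names(weighted) <- rownames(per_pc)
  weighted <- weighted / sum(weighted)

  structure(list(weighted_proportions = weighted,
                 retained_pc_count = m,
                 eigenvalues = ev[seq_len(m)],
                 cumulative_explained = cum[m],
                 threshold = threshold,
                 per_pc_components = per_pc),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat("PVCA:", x$retained_pc_count, "PCs retained (",
      round(100 * x$cumulative_explained, 1), "% of overall variance, ",
      "threshold ", round(100 * x$threshold), "%)\n", sep = "")
  props <- sort(x$weighted_proportions, decreasing = TRUE)
  for (f in names(props))
    cat(sprintf("  %-20s %6.1f%%\n", f, 100 * props[f]))
  invisible(x)
}

#' Stacked-bar plot of PVCA proportions
#'
#' @param x A `pvca_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pvca_result <- function(x, ...) {
  graphics::barplot(x$weighted_proportions,
                    ylab = "weighted proportion of variance",
                    las = 2, ...)
  invisible(x)
}
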