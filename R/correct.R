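# Simple batch-adjustment methods: gene-wise mean-centering and
# ratio-to-reference adjustment.  Both operate on log2 values, so the
# "geometric mean" of the raw-scale description is an arithmetic mean here.

#' Gene-wise per-batch mean-centering
#'
#' For every gene, subtracts the within-batch mean so that each batch's mean
#' is exactly zero -- the one-way-ANOVA-style adjustment used by
#' nearest-shrunken-centroid pipelines.  By default the overall gene mean is
#' not restored (the adjusted matrix is centred at zero); set
#' `restore_overall_mean = TRUE` to add back each gene's grand mean.
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet with a `batch` column covering all samples.
#' @param restore_overall_mean Add each gene's overall mean back after
#'   centering (default `FALSE`).
#' @return Adjusted expression matrix with unchanged dimensions and ids.
#' @export
mean_center <- function(expr, sheet, restore_overall_mean = FALSE) {
  validate_expression_matrix(expr)
  batch <- .sheet_col(expr, sheet, "batch")
  tab <- table(batch)
  if (any(tab < 2L))
    stop("singleton batch(es): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  out <- expr
  for (b in unique(batch)) {
    idx <- which(batch == b)
    out[, idx] <- expr[, idx] - rowMeans(expr[, idx, drop = FALSE])
  }
  if (restore_overall_mean) out <- out + rowMeans(expr)
  out
}

#' Ratio-to-reference batch adjustment
#'
#' Scales every sample by the geometric mean of its batch's reference-group
#' samples; on the log2 scale this subtracts, per gene, the arithmetic mean
#' of the reference samples within the same batch.  Reference samples
#' therefore end up with a per-gene mean of exactly zero in every batch.
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet with `batch` and `group` columns.
#' @param reference_group Group label used as the reference (default
#'   `"control"`).
#' @return Adjusted expression matrix with unchanged dimensions and ids.
#' @export
ratio_g <- function(expr, sheet, reference_group = "control") {
  validate_expression_matrix(expr)
  batch <- .sheet_col(expr, sheet, "batch")
  group <- .sheet_col(expr, sheet, "group")
  out <- expr
  for (b in unique(batch)) {
    idx <- which(batch == b)
    ref <- idx[group[idx] == reference_group]
    if (!length(ref))
      stop("batch '", b, "' has no '", reference_group,
           "' reference samples; ratio adjustment cannot be applied")
    out[, idx] <- expr[, idx] - rowMeans(expr[, ref, drop = FALSE])
  }
  out
}
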