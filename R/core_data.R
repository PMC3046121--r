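# Data model: an expression matrix is a plain numeric matrix (genes x samples,
# log2 scale) with unique rownames (gene ids) and colnames (sample ids); a
# sample sheet is a data.frame with one row per sample.  This mirrors the
# limma/sva convention of matrix + annotation frame.

#' Validate an expression matrix
#'
#' Checks the invariants every function in the package assumes: a numeric
#' matrix with at least one gene and two samples, all values finite, and
#' unique, non-empty row (gene) and column (sample) names.  Values are log2
#' intensities throughout the package.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("expression matrix needs >= 1 gene and >= 2 samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicated gene ids in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids in expression matrix")
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Validate a sample sheet
#'
#' A sample sheet is a data.frame with columns `sample_id`, `batch`, `group`,
#' optionally `replicate_group`, and any further covariate columns.  Every
#' batch must contain at least two samples (scale estimation needs a
#' within-batch variance).
#'
#' @param sheet data.frame with one row per sample.
#' @param min_batch_size Minimum samples per batch (default 2; subsetting
#'   operations relax this and leave the check to the methods that need it).
#' @return `sheet`, invisibly, if valid.
#' @export
validate_sample_sheet <- function(sheet, min_batch_size = 2L) {
  if (!is.data.frame(sheet)) stop("sample sheet must be a data.frame")
  req <- c("sample_id", "batch", "group")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (any(is.na(sheet$batch)) || any(!nzchar(as.character(sheet$batch))))
    stop("sample sheet has empty batch labels")
  if (any(is.na(sheet$group)) || any(!nzchar(as.character(sheet$group))))
    stop("sample sheet has empty group labels")
  tab <- table(as.character(sheet$batch))
  small <- names(tab)[tab < min_batch_size]
  if (length(small))
    stop("batch(es) with a single sample: ", paste(small, collapse = ", "))
  invisible(sheet)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated file whose header row holds sample ids, whose
#' first column holds gene ids, and whose body is numeric (missing marker
#' `NA`).  Optionally applies a present-call-style row filter: rows observed
#' in fewer than `min_present_fraction` of the samples are dropped, and any
#' missing entries remaining after the filter are an error (the downstream
#' methods require a dense matrix).
#'
#' @param path Path to the TSV file.
#' @param min_present_fraction Optional fraction in \[0, 1\]; rows with fewer
#'   than this fraction of non-missing entries are dropped.
#' @return Numeric genes-by-samples matrix (see
#'   [validate_expression_matrix()]).
#' @export
read_expression_tsv <- function(path, min_present_fraction = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression TSV needs a gene-id column and >= 2 samples")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids in ", path)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicated sample column headers in ", path)
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- !is.na(body[[j]]) & is.na(suppressWarnings(as.numeric(body[[j]])))
      if (any(bad))
        stop("non-numeric value in column '", sample_ids[j], "' of ", path)
      body[[j]] <- as.numeric(body[[j]])
    }
  }
  x <- as.matrix(body)
  dimnames(x) <- list(gene_ids, sample_ids)
  if (!is.null(min_present_fraction)) {
    stopifnot(min_present_fraction >= 0, min_present_fraction <= 1)
    keep <- rowMeans(!is.na(x)) >= min_present_fraction
    x <- x[keep, , drop = FALSE]
  }
  if (anyNA(x))
    stop("missing values remain in ", path,
         if (is.null(min_present_fraction)) "" else " after present-fraction filter")
  validate_expression_matrix(x)
  x
}

#' Write a gene-by-sample expression TSV
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @param digits Significant digits to print (default 15, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, digits = 15L) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x),
                   signif(x, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Requires columns `sample_id`, `batch`, `group`; `replicate_group` and any
#' further columns (covariates, numeric or categorical) are carried along
#' unchanged.
#'
#' @param path Path to the TSV file.
#' @return Validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  validate_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet TSV
#'
#' @param sheet Sample sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with a sample sheet
#'
#' Restricts both objects to their common samples, with the sheet reordered
#' to the matrix column order.  In strict mode a matrix sample without
#' annotation is an error rather than being silently dropped.
#'
#' @param expr Expression matrix.
#' @param sheet Sample sheet.
#' @param strict If `TRUE`, every matrix sample must appear in the sheet.
#' @return List with elements `expr` and `sheet`, over the common samples.
#' @export
align_samples <- function(expr, sheet, strict = FALSE) {
  validate_expression_matrix(expr)
  if (!is.data.frame(sheet) || !"sample_id" %in% names(sheet))
    stop("sheet must be a data.frame with a sample_id column")
  common <- intersect(colnames(expr), sheet$sample_id)
  if (!length(common))
    stop("no samples in common between expression matrix and sample sheet")
  if (strict && !all(colnames(expr) %in% sheet$sample_id))
    stop("samples missing from sheet: ",
         paste(setdiff(colnames(expr), sheet$sample_id), collapse = ", "))
  keep <- colnames(expr)[colnames(expr) %in% common]
  expr2 <- expr[, keep, drop = FALSE]
  sheet2 <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  rownames(sheet2) <- NULL
  validate_sample_sheet(sheet2, min_batch_size = 1L)
  list(expr = expr2, sheet = sheet2)
}

# Internal: batch / group labels as character vectors in matrix column order.
.sheet_col <- function(expr, sheet, column) {
  al <- align_samples(expr, sheet, strict = TRUE)
  if (ncol(al$expr) != ncol(expr))
    stop("sample sheet does not cover all matrix samples")
  as.character(al$sheet[[column]])
}
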