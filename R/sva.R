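# Surrogate-variable adjustment: estimate hidden structure from the
# residual matrix left after removing the primary (biological) effect, and
# regress it out.
#
# Step 1: per-gene least squares on the primary variable; collect residuals.
# Step 2: SVD of the residual matrix; the variance share of each right
#         singular vector is compared with a permutation null built by
#         permuting every residual row independently (Buja-Eyuboglu style).
#         Components are retained from the top down while their share stays
#         significant at `alpha`.
# Step 3: retained surrogate vectors are removed from the data by per-gene
#         regression that re-fits (and therefore preserves) the primary
#         effect.

#' Surrogate-variable batch adjustment
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet; `primary` names the column holding the
#'   biological variable to preserve (>= 2 levels).
#' @param primary Sheet column with the primary (protected) variable.
#' @param n_perm Number of row permutations for the null (>= 100).
#' @param alpha Significance level for retaining a component.
#' @param seed Integer seed for the permutations.
#' @param action `"remove"` (default) returns the matrix with surrogates
#'   regressed out; `"return"` leaves the matrix untouched and only reports
#'   the surrogate fit (for use as covariates downstream).
#' @return List with `expr` (adjusted matrix) and `fit`, an `sva_fit` with
#'   `n_sv` (retained components), `sv` (N x n_sv orthonormal surrogate
#'   vectors), `p_values` (permutation p-value per candidate component) and
#'   `var_share` (observed variance share per component).  With zero
#'   retained components the input is returned unchanged.
#' @export
sva_adjust <- function(expr, sheet, primary = "group", n_perm = 100L,
                       alpha = 0.05, seed = 1L, action = c("remove", "return")) {
  action <- match.arg(action)
  validate_expression_matrix(expr)
  stopifnot(n_perm >= 100L, alpha > 0, alpha < 1)
  prim <- .sheet_col(expr, sheet, primary)
  if (length(unique(prim)) < 2L)
    stop("primary variable '", primary, "' has fewer than 2 levels")

  N <- ncol(expr)
  G <- nrow(expr)
  X <- stats::model.matrix(~ factor(prim))
  H <- X %*% solve(crossprod(X), t(X))
  R <- expr - expr %*% t(H)          # residuals: project out primary fit

  share_of <- function(M) {
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    ev / sum(ev)
  }
  obs_share <- share_of(R)
  n_cand <- min(N - qr(X)$rank, length(obs_share))

  set.seed(.stage_seed(seed, "sva_perm"))
  exceed <- numeric(n_cand)
  for (p in seq_len(n_perm)) {
    ord <- t(apply(matrix(stats::runif(G * N), G, N), 1L, order))
    Rp <- matrix(R[cbind(rep(seq_len(G), N), as.vector(ord))], G, N)
    ps <- share_of(Rp)
    exceed <- exceed + (ps[seq_len(n_cand)] >= obs_share[seq_len(n_cand)])
  }
  p_values <- (exceed + 1) / (n_perm + 1)
  n_sv <- 0L
  for (k in seq_len(n_cand)) {
    if (p_values[k] <= alpha) n_sv <- k else break
  }

  if (n_sv == 0L) {
    fit <- structure(list(n_sv = 0L, sv = matrix(nrow = N, ncol = 0L),
                          p_values = p_values,
                          var_share = obs_share[seq_len(n_cand)],
                          primary = primary, removed = FALSE),
                     class = "sva_fit")
    return(list(expr = expr, fit = fit))
  }

  sv <- svd(R, nu = 0L, nv = n_sv)$v          # orthonormal, length-N columns
  adj <- expr
  if (action == "remove") {
    M <- cbind(X, sv)
    B <- solve(crossprod(M), t(M) %*% t(expr))
    w <- B[(ncol(X) + 1L):ncol(M), , drop = FALSE]
    adj <- expr - t(sv %*% w)
    dimnames(adj) <- dimnames(expr)
  }
  fit <- structure(list(n_sv = n_sv, sv = sv,
                        p_values = p_values,
                        var_share = obs_share[seq_len(n_cand)],
                        primary = primary, removed = action == "remove"),
                   class = "sva_fit")
  list(expr = adj, fit = fit)
}

#' @export
print.sva_fit <- function(x, ...) {
  cat("Surrogate-variable fit:", x$n_sv, "component(s) retained",
      if (x$removed) "(regressed out)" else "(reported only)", "\n")
  if (length(x$p_values))
    cat("  leading variance shares:",
        paste(signif(utils::head(x$var_share, 5), 3), collapse = ", "),
        "\n  permutation p-values:  ",
        paste(signif(utils::head(x$p_values, 5), 3), collapse = ", "), "\n")
  invisible(x)
}
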