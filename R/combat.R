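# Empirical-Bayes location/scale batch adjustment.
#
# Each gene is standardized by a least-squares fit on intercept + protected
# covariates + batch indicators (batch coefficients weighted to sum to
# zero); per-batch location (gamma_hat) and scale (delta_hat^2) estimates on
# the standardized data are then shrunk toward batch-level priors --
# Normal(gamma_bar, tau^2) for locations and InverseGamma(lambda, theta) for
# squared scales in parametric mode, or a likelihood-weighted average over
# the other genes' estimates in non-parametric mode -- and the data are
# adjusted with the shrunken estimates, restoring the protected covariate
# signal.

.VAR_FLOOR <- 1e-8

# fixed-point iteration for the parametric posterior (per batch)
.eb_iterate <- function(sdat, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                        conv = 1e-4, max_iter = 500L) {
  n <- ncol(sdat)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), .VAR_FLOOR),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star2 = pmax(d_new, .VAR_FLOOR))
}

# non-parametric posterior: likelihood-weighted average of the other genes'
# (gamma_hat, delta_hat^2) pairs, weights = normal likelihood of this gene's
# standardized batch values; exact (all genes), chunked, in log space
.eb_nonparametric <- function(sdat, g_hat, d_hat, block = 512L) {
  G <- nrow(sdat)
  n <- ncol(sdat)
  rs <- rowSums(sdat)
  rs2 <- rowSums(sdat^2)
  log_norm <- -n / 2 * log(2 * pi * d_hat)   # per candidate gene g'
  g_star <- numeric(G)
  d_star <- numeric(G)
  for (start in seq(1L, G, by = block)) {
    idx <- start:min(start + block - 1L, G)
    # log-likelihood of gene g's data under gene g' parameters (rows g, cols g')
    quad <- outer(rs2[idx], 1 / (2 * d_hat)) -
      outer(rs[idx], g_hat / d_hat) +
      matrix(n * g_hat^2 / (2 * d_hat), length(idx), G, byrow = TRUE)
    ll <- matrix(log_norm, length(idx), G, byrow = TRUE) - quad
    ll[cbind(seq_along(idx), idx)] <- -Inf   # leave gene g itself out
    m <- apply(ll, 1L, max)
    w <- exp(ll - m)
    sw <- rowSums(w)
    g_star[idx] <- (w %*% g_hat) / sw
    d_star[idx] <- (w %*% d_hat) / sw
  }
  list(gamma_star = g_star, delta_star2 = pmax(d_star, .VAR_FLOOR))
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Removes per-batch additive and multiplicative effects by shrinking
#' per-batch-per-gene estimates toward batch-level priors (see the package
#' vignette for the model).  Covariates listed in `covariates` -- by default
#' the biological `group` label -- are protected: their fitted signal is
#' restored in the adjusted matrix.  Pass `covariates = NULL` to adjust
#' blind to the biology (in a batch-confounded design this removes the
#' biological signal together with the batch effect).
#'
#' @param expr Expression matrix (genes x samples, log2).
#' @param sheet Sample sheet with a `batch` column (>= 2 batches, each with
#'   >= 2 samples) and any covariate columns.
#' @param covariates Character vector of sheet columns to protect, or `NULL`.
#' @param parametric Use the parametric (Normal / inverse-gamma) priors
#'   (`TRUE`, default) or the non-parametric likelihood-weighted posterior.
#' @return List with `expr` (adjusted matrix, same dimensions and ids) and
#'   `fit`, a `combat_fit` object exposing all estimates: per-gene
#'   standardization parameters (`alpha_hat`, `beta_hat`, `pooled_var`),
#'   per-batch raw estimates (`gamma_hat`, `delta_hat2`), shrunken estimates
#'   (`gamma_star`, `delta_star2`) and parametric hyperparameters
#'   (`gamma_bar`, `tau2`, `lambda`, `theta`).
#' @export
combat <- function(expr, sheet, covariates = "group", parametric = TRUE) {
  validate_expression_matrix(expr)
  batch <- .sheet_col(expr, sheet, "batch")
  batches <- unique(batch)
  if (length(batches) < 2L) stop("empirical-Bayes adjustment needs >= 2 batches")
  tab <- table(batch)
  if (any(tab < 2L))
    stop("singleton batch(es): ", paste(names(tab)[tab < 2L], collapse = ", "))

  N <- ncol(expr)
  G <- nrow(expr)
  batch_design <- stats::model.matrix(~ 0 + factor(batch, levels = batches))
  colnames(batch_design) <- batches
  if (length(covariates)) {
    al <- align_samples(expr, sheet, strict = TRUE)
    covdf <- al$sheet[, covariates, drop = FALSE]
    mod <- stats::model.matrix(~ ., data = covdf)[, -1L, drop = FALSE]
  } else {
    mod <- matrix(nrow = N, ncol = 0L)
  }
  design <- cbind(batch_design, mod)
  if (qr(design)$rank < ncol(design))
    stop("design is rank deficient: a covariate is confounded with batch; ",
         "remove it from `covariates` (it cannot be protected)")

  n_i <- colSums(batch_design)
  B_hat <- solve(crossprod(design), t(design) %*% t(expr))
  alpha_hat <- as.numeric((n_i / N) %*% B_hat[seq_along(batches), , drop = FALSE])
  beta_hat <- B_hat[-seq_along(batches), , drop = FALSE]
  resid <- expr - t(design %*% B_hat)
  pooled_var <- pmax(rowMeans(resid^2), .VAR_FLOOR)

  stand_mean <- matrix(alpha_hat, G, N)
  if (ncol(mod)) stand_mean <- stand_mean + t(mod %*% beta_hat)
  Z <- (expr - stand_mean) / sqrt(pooled_var)

  gamma_hat <- matrix(NA_real_, length(batches), G,
                      dimnames = list(batches, rownames(expr)))
  delta_hat2 <- gamma_hat
  gamma_star <- gamma_hat
  delta_star2 <- gamma_hat
  gamma_bar <- tau2 <- lambda <- theta <- stats::setNames(
    rep(NA_real_, length(batches)), batches)

  for (b in batches) {
    idx <- which(batch == b)
    Zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- pmax(apply(Zb, 1L, stats::var), .VAR_FLOOR)
    gamma_hat[b, ] <- g_hat
    delta_hat2[b, ] <- d_hat
    if (parametric) {
      gamma_bar[b] <- mean(g_hat)
      tau2[b] <- stats::var(g_hat)
      m <- mean(d_hat)
      v <- stats::var(d_hat)
      lambda[b] <- m^2 / v + 2           # inverse-gamma shape, moment matched
      theta[b] <- m * (lambda[b] - 1)    # inverse-gamma scale
      sol <- .eb_iterate(Zb, g_hat, d_hat, gamma_bar[b], tau2[b],
                         lambda[b], theta[b])
    } else {
      sol <- .eb_nonparametric(Zb, g_hat, d_hat)
    }
    gamma_star[b, ] <- sol$gamma_star
    delta_star2[b, ] <- sol$delta_star2
  }

  adj <- Z
  for (b in batches) {
    idx <- which(batch == b)
    adj[, idx] <- (Z[, idx, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star2[b, ])
  }
  adj <- adj * sqrt(pooled_var) + stand_mean
  dimnames(adj) <- dimnames(expr)

  fit <- structure(
    list(alpha_hat = stats::setNames(alpha_hat, rownames(expr)),
         beta_hat = beta_hat, pooled_var = pooled_var,
         gamma_hat = gamma_hat, delta_hat2 = delta_hat2,
         gamma_star = gamma_star, delta_star2 = delta_star2,
         gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta,
         parametric = parametric, batches = batches, n_per_batch = n_i,
         covariates = covariates),
    class = "combat_fit")
  list(expr = adj, fit = fit)
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("Empirical-Bayes location/scale fit (",
      if (x$parametric) "parametric" else "non-parametric", " priors)\n",
      sep = "")
  cat("  batches:", paste0(x$batches, " (n=", x$n_per_batch, ")",
                           collapse = ", "), "\n")
  if (length(x$covariates))
    cat("  protected covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (x$parametric) {
    cat("  location prior means (gamma_bar):",
        paste(signif(x$gamma_bar, 3), collapse = ", "), "\n")
    cat("  scale prior (lambda):",
        paste(signif(x$lambda, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.combat_fit <- function(object, ...) {
  out <- data.frame(
    batch = object$batches,
    n = as.integer(object$n_per_batch),
    mean_gamma_hat = rowMeans(object$gamma_hat),
    mean_gamma_star = rowMeans(object$gamma_star),
    mean_delta_hat2 = rowMeans(object$delta_hat2),
    mean_delta_star2 = rowMeans(object$delta_star2),
    row.names = NULL)
  out
}
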