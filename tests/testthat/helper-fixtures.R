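# Shared fixture builders; everything is generated in code.

# tiny deterministic expression matrix
toy_expr <- function(values, n_genes, n_samples,
                     gene_ids = sprintf("g%02d", seq_len(n_genes)),
                     sample_ids = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
}

toy_sheet <- function(n, batches, groups,
                      sample_ids = sprintf("s%02d", seq_len(n)), ...) {
  data.frame(sample_id = sample_ids,
             batch = rep_len(batches, n), group = rep_len(groups, n),
             ..., stringsAsFactors = FALSE)
}

# small two-batch null simulation used by several correction tests
null_sim <- function(n_genes = 200L, n_per_batch = 50L, gamma_sd = 0.55,
                     seed = 42L) {
  layout <- data.frame(batch = c("B1", "B2"),
                       n_case = c(n_per_batch / 2, n_per_batch / 2),
                       n_control = c(n_per_batch / 2, n_per_batch / 2))
  simulate_aas(layout = layout, spec = batch_effect_spec(gamma_sd = gamma_sd),
               seed = seed, n_genes = n_genes,
               n_de = 12L, n_case = n_per_batch, n_control = n_per_batch)
}

# independent one-way random-effects ICC oracle from explicit sums of squares
icc_oracle <- function(y, subject, replicate) {
  k <- length(unique(replicate))
  n <- length(unique(subject))
  grand <- mean(y)
  sm <- tapply(y, subject, mean)
  msb <- k * sum((sm - grand)^2) / (n - 1)
  msw <- sum((y - sm[as.character(subject)])^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Mann-Whitney pairwise-concordance AUC oracle (ties count 1/2)
auc_oracle <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}
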