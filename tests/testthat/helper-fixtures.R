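# Shared fixtures: small expression containers built in code.

# expr_matrix from a plain matrix, auto-naming genes/samples when absent
make_expr <- function(m, detected = NULL, log2 = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (!is.null(detected)) dimnames(detected) <- dimnames(m)
  expr_matrix(m, detected, log2 = log2)
}

# phenotype table with the given survival values (and derived labels)
make_phen <- function(survival, sample_ids = sprintf("s%02d",
                                                     seq_along(survival))) {
  label_quality(data.frame(sample_id = sample_ids, survival = survival,
                           stringsAsFactors = FALSE))
}

# a vector with exact sample correlation `rho` to y (uses an orthogonalized
# noise direction); empirical cor(x, y) equals rho to machine precision
vector_with_cor <- function(y, rho, seed = 1) {
  e <- withr::with_seed(seed, stats::rnorm(length(y)))
  e <- stats::residuals(stats::lm(e ~ y))
  zy <- as.vector(scale(y))
  ze <- as.vector(scale(e))
  rho * zy + sqrt(1 - rho^2) * ze
}

# brute-force BH step-up oracle: q(i) = min_{j >= i} (m/j) p_(j), capped at
# 1 and returned in input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min((m / (i:m)) * p[o[i:m]]))
  }
  q
}

# small no-signal synthetic dataset for null checks
null_dataset <- function(n_samples, n_genes, seed) {
  generate_dataset(synth_config(
    n_samples = n_samples, n_genes = n_genes, n_signal_genes = 0,
    effect_weights = numeric(0), noise_sd = 30, frac_absent_genes = 0,
    n_duplicate_blocks = 0, seed = seed))
}
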