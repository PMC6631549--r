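# Permutation null model: re-run the GA search on survival-permuted data,
# compare per-gene selection frequencies against the 95th/99th percentile of
# the null frequency distribution, and compare actual vs null R^2
# distributions with a one-sided Mann-Whitney test.

#' Randomly permute survival rates across samples
#'
#' Uniform random permutation preserving the multiset of values;
#' deterministic per seed.
#'
#' @param y Numeric survival vector (length >= 2).
#' @param seed Integer seed.
#' @return Permuted vector.
#' @export
permute_survival <- function(y, seed) {
  if (length(y) < 2) .fail("need >= 2 observations to permute")
  withr::with_seed(seed, sample(y))
}

#' Run the GA search on permuted survival data
#'
#' Executes `n_perms` independent GA populations, each on a fresh random
#' permutation of the survival vector (one permutation per null population),
#' mirroring the actual multi-population run.
#'
#' @inheritParams run_ga
#' @param n_perms Number of permuted populations; defaults to
#'   `config$n_populations` (a matched design).
#' @return A `ga_solutions` object with `source = "permuted"`.
#' @export
run_null <- function(X, y, pool_ids, config,
                     n_perms = config$n_populations) {
  stopifnot(inherits(config, "ga_config"))
  n_perms <- .check_count(n_perms, "n_perms", min = 1)
  seeds <- vapply(seq_len(n_perms),
                  function(p) derive_seed(config$seed, 200, p), integer(1))
  runs <- lapply(seq_len(n_perms), function(p) {
    yp <- permute_survival(y, derive_seed(config$seed, 300, p))
    run_ga(X, yp, pool_ids, config, seed = seeds[p])
  })
  structure(list(
    individuals = do.call(c, lapply(runs, `[[`, "individuals")),
    fitness = do.call(c, lapply(runs, `[[`, "fitness")),
    population = rep(seq_len(n_perms), each = config$population_size),
    seeds = seeds, config = config, source = "permuted"),
    class = "ga_solutions")
}

#' Per-gene selection frequencies across final GA solutions
#'
#' For every pool gene, the fraction of final solutions that contain it;
#' genes never selected get 0. The sum of frequencies times the number of
#' solutions equals the total number of gene slots across solutions.
#'
#' @param solutions A `ga_solutions` object (or plain list of gene-id
#'   vectors).
#' @param pool_ids Character vector of pool gene identifiers.
#' @return data.frame `gene_id`, `frequency`.
#' @export
selection_frequencies <- function(solutions, pool_ids) {
  inds <- if (inherits(solutions, "ga_solutions")) solutions$individuals
          else solutions
  if (length(inds) == 0) .fail("empty solution set")
  all_genes <- unlist(inds, use.names = FALSE)
  idx <- match(all_genes, pool_ids)
  if (anyNA(idx)) {
    .fail("solution gene(s) absent from pool: %s",
          paste(unique(all_genes[is.na(idx)]), collapse = ", "))
  }
  counts <- tabulate(idx, nbins = length(pool_ids))
  data.frame(gene_id = pool_ids, frequency = counts / length(inds),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentile cutoff of a null selection-frequency profile
#'
#' The stated percentile of the per-gene null frequencies, computed with
#' linear interpolation between order statistics
#' (`stats::quantile`, type 7).
#'
#' @param null_profile data.frame from [selection_frequencies()] on permuted
#'   runs (or a numeric frequency vector).
#' @param percentile Percentile in (0, 100), typically 95 or 99.
#' @return The frequency cutoff (scalar).
#' @export
frequency_threshold <- function(null_profile, percentile) {
  f <- if (is.data.frame(null_profile)) null_profile$frequency
       else null_profile
  if (length(f) == 0) .fail("empty null profile")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    .fail("'percentile' must lie in (0, 100)")
  }
  unname(stats::quantile(f, percentile / 100, type = 7, names = FALSE))
}

#' Genes whose actual selection frequency exceeds a null cutoff
#'
#' Strict exceedance: a gene is significant when its frequency in the actual
#' runs is strictly greater than the cutoff.
#'
#' @param actual_profile data.frame from [selection_frequencies()] on the
#'   actual runs.
#' @param cutoff Frequency cutoff from [frequency_threshold()].
#' @return Character vector of significant gene ids.
#' @export
significant_genes <- function(actual_profile, cutoff) {
  actual_profile$gene_id[actual_profile$frequency > cutoff]
}

#' One-sided Mann-Whitney comparison of actual vs null R-squared values
#'
#' Tests whether the actual final-solution R^2 values are stochastically
#' larger than the permuted-data ones. Exact when both samples have at most
#' 20 untied observations; otherwise the tie-corrected normal approximation.
#'
#' @param actual_r2,null_r2 Numeric vectors of final-solution R^2 values.
#' @return The one-sided p-value (actual > null).
#' @export
compare_r2_distributions <- function(actual_r2, null_r2) {
  if (length(actual_r2) == 0 || length(null_r2) == 0) {
    .fail("both R^2 vectors must be non-empty")
  }
  exact <- length(actual_r2) <= 20 && length(null_r2) <= 20 &&
    !anyDuplicated(c(actual_r2, null_r2))
  suppressWarnings(
    stats::wilcox.test(actual_r2, null_r2, alternative = "greater",
                       exact = exact)$p.value)
}

#' Compare actual and permuted GA runs
#'
#' Bundles the full null-model comparison: per-gene selection frequencies on
#' actual and permuted solutions, 95th/99th-percentile null cutoffs,
#' significant gene sets at both cutoffs, and the one-sided Mann-Whitney
#' p-value comparing the R^2 distributions.
#'
#' @param actual A `ga_solutions` from [run_multi()].
#' @param null A `ga_solutions` from [run_null()].
#' @param pool_ids Character vector of pool gene identifiers.
#' @return A list of class `null_comparison`: `actual_freq`, `null_freq`,
#'   `threshold_95`, `threshold_99`, `significant_genes_95`,
#'   `significant_genes_99`, `mannwhitney_p`, `actual_r2`, `null_r2`.
#' @export
compare_runs <- function(actual, null, pool_ids) {
  af <- selection_frequencies(actual, pool_ids)
  nf <- selection_frequencies(null, pool_ids)
  t95 <- frequency_threshold(nf, 95)
  t99 <- frequency_threshold(nf, 99)
  structure(list(
    actual_freq = af, null_freq = nf,
    threshold_95 = t95, threshold_99 = t99,
    significant_genes_95 = significant_genes(af, t95),
    significant_genes_99 = significant_genes(af, t99),
    mannwhitney_p = compare_r2_distributions(actual$fitness, null$fitness),
    actual_r2 = actual$fitness, null_r2 = null$fitness),
    class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "null_comparison: %d genes > 95th pct cutoff (%.4f), ",
    "%d genes > 99th pct cutoff (%.4f)\n",
    "  Mann-Whitney one-sided p (actual R2 > null R2): %.3g\n"),
    length(x$significant_genes_95), x$threshold_95,
    length(x$significant_genes_99), x$threshold_99, x$mannwhitney_p))
  invisible(x)
}
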