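# End-to-end orchestration: simulate (or load) -> normalize -> quality
# labels -> presence filter -> differential expression -> gene pool ->
# GA search -> permutation null -> report, with every stage seeded from one
# master seed and a run manifest recording configs, seeds and output
# checksums.

#' Run the full egg-quality signature pipeline
#'
#' Chains the package's stages on a synthetic dataset (or a caller-supplied
#' one): normalization, quality labeling, presence filtering, differential
#' expression between good and bad clutches, correlation + redundancy
#' prefiltering into a gene pool, the multi-population GA search, the
#' matched permutation-null search, and the null-model comparison. All
#' randomness derives from `synth$seed` and `ga$seed`. When `out_dir` is
#' given, every table is written as TSV plus a JSON manifest with md5
#' checksums; re-running with the same configs reproduces identical files.
#'
#' @param synth A [synth_config()] describing the simulated study, or a list
#'   `list(expression =, phenotypes =)` with observed data (expression raw or
#'   log2; phenotypes with survival %).
#' @param ga A [ga_config()].
#' @param n_perms Number of permuted GA populations (default: matched to
#'   `ga$n_populations`).
#' @param de_alpha BH-corrected significance level for differential
#'   expression.
#' @param prefilter_alpha Correlation-test retention threshold.
#' @param r_threshold Redundancy-pruning correlation threshold.
#' @param out_dir Optional output directory for TSV tables and the manifest.
#' @return A list of class `pipeline_result`: the normalized matrix, labeled
#'   phenotypes, DE table, gene pool, actual and null `ga_solutions`, the
#'   `null_comparison`, and (if written) the manifest.
#' @export
run_pipeline <- function(synth = synth_config(n_samples = 136,
                                              effect_weights =
                                                c(9, 8, 7, 6),
                                              noise_sd = 5.5),
                         ga = ga_config(population_size = 50,
                                        n_generations = 30,
                                        n_populations = 3),
                         n_perms = ga$n_populations,
                         de_alpha = 0.05,
                         prefilter_alpha = 0.1,
                         r_threshold = 0.95,
                         out_dir = NULL) {
  t0 <- Sys.time()
  stages <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .fail("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (inherits(synth, "synth_config")) {
    dataset <- step("simulate", generate_dataset(synth))
  } else {
    dataset <- synth
    if (!inherits(dataset$expression, "expr_matrix")) {
      .fail("'synth' must be a synth_config or a list with an expr_matrix")
    }
  }
  phen <- step("label", label_quality(dataset$phenotypes))
  norm <- step("normalize", normalize_expression(dataset$expression))
  filt <- step("presence_filter", presence_filter(norm, phen))
  de <- step("differential_expression",
             differential_expression(filt, phen, alpha = de_alpha))
  survival <- .aligned_survival(phen, sample_ids(filt))
  pool <- step("prefilter",
               build_gene_pool(filt, survival, alpha = prefilter_alpha,
                               r_threshold = r_threshold))
  if (nrow(pool) < ga$max_genes) {
    .fail("gene pool (%d) smaller than max_genes (%d); relax the prefilter",
          nrow(pool), ga$max_genes)
  }
  X <- t(filt$values[pool$gene_id, , drop = FALSE])
  actual <- step("ga_search", run_multi(X, survival, pool$gene_id, ga))
  null <- step("null_run",
               run_null(X, survival, pool$gene_id, ga, n_perms = n_perms))
  report <- step("report", compare_runs(actual, null, pool$gene_id))

  result <- structure(list(
    expression = norm, phenotypes = phen, de_table = de, pool = pool,
    actual = actual, null = null, report = report,
    truth = dataset$truth, manifest = NULL), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    sol_df <- function(s) data.frame(
      population = s$population,
      individual = seq_along(s$individuals),
      genes = vapply(s$individuals, paste, "", collapse = ";"),
      mean_2fcv_r2 = s$fitness, stringsAsFactors = FALSE)
    files <- c(
      wt(phen, "phenotypes.tsv"),
      wt(de, "de_table.tsv"),
      wt(pool, "pool.tsv"),
      wt(sol_df(actual), "solutions.tsv"),
      wt(sol_df(null), "null_solutions.tsv"),
      wt(report$actual_freq, "actual_frequencies.tsv"),
      wt(report$null_freq, "null_frequencies.tsv"),
      wt(data.frame(
        gene_id = c(report$significant_genes_95),
        above_99 = report$significant_genes_95 %in%
          report$significant_genes_99), "significant_genes.tsv"))
    manifest <- list(
      version = as.character(utils::packageVersion("plsga")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      master_seeds = list(synth = if (inherits(synth, "synth_config"))
        synth$seed else NA, ga = ga$seed),
      thresholds = list(de_alpha = de_alpha,
                        prefilter_alpha = prefilter_alpha,
                        r_threshold = r_threshold,
                        frequency_95 = report$threshold_95,
                        frequency_99 = report$threshold_99),
      mannwhitney_p = report$mannwhitney_p,
      files = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

#' Verify the checksums recorded in a pipeline manifest
#'
#' Recomputes md5 sums of every file referenced by `manifest.json` in
#' `out_dir` and reports mismatches (e.g. tampered or missing
#' intermediates).
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Invisibly `TRUE` when all checksums match; otherwise an error
#'   naming the first mismatching file.
#' @export
verify_manifest <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  if (!file.exists(mpath)) .fail("no manifest.json in %s", out_dir)
  manifest <- jsonlite::read_json(mpath)
  for (f in names(manifest$files)) {
    if (!file.exists(f)) .fail("manifest file missing: %s", f)
    now <- unname(tools::md5sum(f))
    if (!identical(now, manifest$files[[f]])) {
      .fail("checksum mismatch for %s", f)
    }
  }
  invisible(TRUE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "pipeline_result:\n",
    "  %d genes after presence filter, %d significant DE genes\n",
    "  gene pool: %d genes; GA: %d actual / %d null solutions\n",
    "  best mean 2-FCV R2 = %.4f; Mann-Whitney p = %.3g\n",
    "  significant genes: %d (95th pct), %d (99th pct)\n"),
    nrow(x$de_table), sum(x$de_table$significant),
    nrow(x$pool), length(x$actual$individuals), length(x$null$individuals),
    max(x$actual$fitness), x$report$mannwhitney_p,
    length(x$report$significant_genes_95),
    length(x$report$significant_genes_99)))
  invisible(x)
}
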