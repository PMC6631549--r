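# Gene-pool construction before the GA search: discard genes whose Pearson
# correlation with survival is not nominally significant, then collapse
# groups of near-duplicate genes (pairwise r above a threshold) to the single
# member most correlated with survival.

# Pearson r of every gene with survival plus the t-distribution p-value
# (t = r sqrt(n-2)/sqrt(1-r^2), df = n-2); constant genes get r = 0, p = 1
.survival_cor <- function(v, survival) {
  n <- ncol(v)
  r <- suppressWarnings(as.vector(stats::cor(t(v), survival)))
  r[!is.finite(r)] <- 0
  r2 <- pmin(r^2, 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[r2 >= 1] <- 0
  list(r = r, p = p)
}

#' Correlation filter against survival rate
#'
#' Tests each gene's Pearson correlation with survival (two-sided t test with
#' n - 2 degrees of freedom) and retains genes with p-value at most `alpha`.
#' No multiple-testing correction is applied at this stage. Constant genes
#' are defined to have r = 0, p = 1 and are discarded.
#'
#' @param x Log-space [expr_matrix()].
#' @param survival Numeric survival vector aligned to the matrix samples (or
#'   a phenotype data.frame with `sample_id`/`survival`).
#' @param alpha Retention threshold on the correlation-test p-value,
#'   default 0.1.
#' @return data.frame per gene: `gene_id`, `r_survival`, `p_value`,
#'   `retained`.
#' @export
correlation_filter <- function(x, survival, alpha = 0.1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(survival)) {
    survival <- .aligned_survival(survival, sample_ids(x))
  }
  if (ncol(x$values) < 4) .fail("need >= 4 samples for the correlation test")
  if (stats::sd(survival) == 0) .fail("survival must not be constant")
  sc <- .survival_cor(x$values, survival)
  data.frame(gene_id = gene_ids(x), r_survival = sc$r, p_value = sc$p,
             retained = sc$p <= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Redundancy pruning of near-duplicate genes
#'
#' Builds the graph whose edges connect gene pairs with pairwise correlation
#' above `r_threshold` (raw r by default; `use_abs = TRUE` uses |r|), takes
#' connected components as redundancy groups, and keeps from each component
#' only the gene with the highest |r| to survival (ties broken by input
#' order). Genes in no edge are kept.
#'
#' @inheritParams correlation_filter
#' @param r_threshold Pairwise-correlation threshold, default 0.95 (strict
#'   exceedance).
#' @param use_abs Threshold |r| instead of raw r.
#' @return data.frame per gene: `gene_id`, `r_survival`, `component`, `kept`.
#' @export
redundancy_prune <- function(x, survival, r_threshold = 0.95,
                             use_abs = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(survival)) {
    survival <- .aligned_survival(survival, sample_ids(x))
  }
  v <- x$values
  rs <- .survival_cor(v, survival)$r
  cc <- .safe_row_cor(v)
  w <- if (use_abs) abs(cc) else cc
  adj <- w > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  kept <- logical(nrow(v))
  for (k in unique(comp)) {
    members <- which(comp == k)
    kept[members[which.max(abs(rs[members]))]] <- TRUE
  }
  data.frame(gene_id = gene_ids(x), r_survival = rs,
             component = as.integer(comp), kept = kept,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the GA gene pool: correlation filter then redundancy pruning
#'
#' Applies [correlation_filter()] and then [redundancy_prune()] on the
#' retained genes, recording provenance (thresholds and before/after counts)
#' as attributes.
#'
#' @inheritParams redundancy_prune
#' @param alpha Correlation-test retention threshold, default 0.1.
#' @return data.frame per pooled gene: `gene_id`, `r_survival`, `p_value`,
#'   `component`; attribute `provenance` holds thresholds and counts.
#' @export
build_gene_pool <- function(x, survival, alpha = 0.1, r_threshold = 0.95,
                            use_abs = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(survival)) {
    survival <- .aligned_survival(survival, sample_ids(x))
  }
  cf <- correlation_filter(x, survival, alpha = alpha)
  xs <- .subset_genes(x, cf$retained)
  if (nrow(xs$values) == 0) .fail("no gene passed the correlation filter")
  rp <- redundancy_prune(xs, survival, r_threshold = r_threshold,
                         use_abs = use_abs)
  pool <- data.frame(
    gene_id = rp$gene_id[rp$kept],
    r_survival = rp$r_survival[rp$kept],
    p_value = cf$p_value[match(rp$gene_id[rp$kept], cf$gene_id)],
    component = rp$component[rp$kept],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(pool, "provenance") <- list(
    alpha = alpha, r_threshold = r_threshold, use_abs = use_abs,
    n_input = nrow(x$values), n_after_correlation = nrow(xs$values),
    n_after_prune = nrow(pool))
  pool
}
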