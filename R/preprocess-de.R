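# Microarray-style preprocessing and two-group differential expression:
# log2 + per-array median centering, the 80% above-background presence rule,
# per-gene t-tests with Benjamini-Hochberg correction, signed fold changes,
# and hierarchical-clustering leaf orders for heatmap export.

#' Normalize raw intensities: log2 transform and per-array median centering
#'
#' Raw positive intensities are log2-transformed and each sample (array) is
#' centered by subtracting its median log2 intensity, the standard
#' single-channel normalization. A matrix already flagged as log-space is
#' only median-centered (so the operation is idempotent-safe). The detection
#' mask is unchanged.
#'
#' @param x An [expr_matrix()].
#' @return An [expr_matrix()] in log2 units, median-centered per sample.
#' @examples
#' m <- matrix(c(1, 10, 100), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
#' normalize_expression(expr_matrix(m))$values
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!x$log2) {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      .fail("non-positive intensity for gene '%s' in sample '%s'",
            rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]])
    }
    v <- log2(v)
  }
  med <- apply(v, 2, stats::median)
  v <- sweep(v, 2, med)
  expr_matrix(v, x$detected, log2 = TRUE)
}

#' Presence filter: keep genes detected in most samples of a quality group
#'
#' A gene is retained when its above-background detection fraction is at
#' least `min_fraction` within the good group or within the bad group.
#' Unlabeled samples are ignored by the criterion but retained in the output
#' matrix.
#'
#' @param x An [expr_matrix()].
#' @param phenotypes Labeled phenotype table (see [label_quality()]); both
#'   groups must be non-empty among the matrix's samples.
#' @param min_fraction Minimum detected fraction, default 0.8.
#' @return The row-subset [expr_matrix()] of retained genes.
#' @export
presence_filter <- function(x, phenotypes, min_fraction = 0.8) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    .fail("'min_fraction' must lie in (0, 1]")
  }
  grp <- .quality_groups(phenotypes, sample_ids(x))
  fg <- rowMeans(x$detected[, grp$good, drop = FALSE])
  fb <- rowMeans(x$detected[, grp$bad, drop = FALSE])
  .subset_genes(x, fg >= min_fraction | fb >= min_fraction)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (`q(i) = min_{j >= i} p_(j) m / j`, capped at
#' 1, returned in input order).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @examples
#' bh_adjust(c(0.005, 0.009, 0.05, 0.5))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    .fail("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# vectorised per-gene two-sample t-tests (Welch by default) of bad vs good;
# returns t statistics, p-values and Welch/pooled dfs.  Degenerate genes
# (zero variance in both groups) get p = 1 when the means agree, p = 0
# otherwise, the limiting behaviour of the statistic.
.row_t_test <- function(vg, vb, var_equal = FALSE) {
  n1 <- ncol(vg); n2 <- ncol(vb)
  m1 <- rowMeans(vg); m2 <- rowMeans(vb)
  s1 <- rowSums((vg - m1)^2) / (n1 - 1)
  s2 <- rowSums((vb - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    a <- s1 / n1; b <- s2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  if (any(degen)) {
    same <- degen & (m1 == m2)
    t[same] <- 0; p[same] <- 1
    diffm <- degen & (m1 != m2)
    t[diffm] <- sign(m2 - m1)[diffm] * Inf; p[diffm] <- 0
  }
  list(t = t, p = p, mean_good = m1, mean_bad = m2)
}

# signed fold-change convention: ratio r = 2^(log2 difference), reported as r
# when r >= 1 and -1/r otherwise, so down-regulation appears as a negative
# fold change of magnitude >= 1
.signed_fc <- function(delta_log2) {
  r <- 2^delta_log2
  ifelse(r >= 1, r, -1 / r)
}

#' Per-gene differential expression between bad and good quality groups
#'
#' Two-sample t-test (Welch's unequal-variance test by default) per gene
#' between the bad and good groups of a log-space matrix, BH-adjusted
#' q-values, and signed fold changes of bad relative to good.
#'
#' @param x Log-space [expr_matrix()].
#' @param phenotypes Labeled phenotype table; >= 2 samples per group.
#' @param alpha Significance level on the BH-adjusted q-value, default 0.05.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return A data.frame with one row per gene: `gene_id`, `mean_good`,
#'   `mean_bad`, `t`, `p_value`, `q_value`, `fold_change`, `significant`.
#'   `t` and `fold_change` are oriented bad-vs-good.
#' @export
differential_expression <- function(x, phenotypes, alpha = 0.05,
                                    var_equal = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$log2) .fail("differential expression requires a log-space matrix")
  grp <- .quality_groups(phenotypes, sample_ids(x))
  if (length(grp$good) < 2 || length(grp$bad) < 2) {
    .fail("need >= 2 samples per quality group")
  }
  vg <- x$values[, grp$good, drop = FALSE]
  vb <- x$values[, grp$bad, drop = FALSE]
  tt <- .row_t_test(vg, vb, var_equal = var_equal)
  q <- bh_adjust(tt$p)
  data.frame(gene_id = gene_ids(x),
             mean_good = tt$mean_good,
             mean_bad = tt$mean_bad,
             t = tt$t,
             p_value = tt$p,
             q_value = q,
             fold_change = .signed_fc(tt$mean_bad - tt$mean_good),
             significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed fold change of bad relative to good quality eggs
#'
#' Ratio `r = 2^(mean_bad - mean_good)` on the log2 matrix, reported as `r`
#' when `r >= 1` and `-1/r` otherwise (so |fold change| >= 1 always and
#' down-regulation in bad eggs is negative).
#'
#' @inheritParams differential_expression
#' @return Named numeric vector of signed fold changes, one per gene.
#' @export
fold_change <- function(x, phenotypes) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$log2) .fail("fold change requires a log-space matrix")
  grp <- .quality_groups(phenotypes, sample_ids(x))
  delta <- rowMeans(x$values[, grp$bad, drop = FALSE]) -
    rowMeans(x$values[, grp$good, drop = FALSE])
  stats::setNames(.signed_fc(delta), gene_ids(x))
}

# correlation matrix with constant rows mapped to 0 correlation
.safe_row_cor <- function(v) {
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Hierarchical-clustering leaf orders for heatmap export
#'
#' Agglomerative clustering of genes and of samples with distance
#' `1 - Pearson r` and average linkage. Constant profiles get correlation 0
#' (distance 1) to every other profile.
#'
#' @param x Log-space [expr_matrix()], typically restricted to significant
#'   genes; needs >= 2 genes and >= 2 samples.
#' @return A list: `gene_order`, `sample_order` (identifier vectors in leaf
#'   order), and the underlying `hclust` trees `gene_tree`, `sample_tree`.
#' @export
cluster_order <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(x$values) < 2 || ncol(x$values) < 2) {
    .fail("clustering needs >= 2 genes and >= 2 samples")
  }
  gt <- stats::hclust(stats::as.dist(1 - .safe_row_cor(x$values)),
                      method = "average")
  st <- stats::hclust(stats::as.dist(1 - .safe_row_cor(t(x$values))),
                      method = "average")
  list(gene_order = gene_ids(x)[gt$order],
       sample_order = sample_ids(x)[st$order],
       gene_tree = gt, sample_tree = st)
}
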