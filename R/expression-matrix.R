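# The expression container used throughout: a genes x samples numeric matrix
# plus a parallel above-background detection mask and a flag recording whether
# values are raw intensities or log2 units.

#' Construct an expression matrix
#'
#' A lightweight container for a genes x samples expression matrix: numeric
#' values (raw intensities or log2 units), a parallel logical
#' detection (above-background) mask, and a flag recording the value scale.
#' Gene identifiers are the rownames, sample identifiers the colnames; both
#' must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames and colnames.
#' @param detected Logical matrix of the same shape (above-background flags),
#'   or `NULL` for all-detected.
#' @param log2 Logical flag: `TRUE` when `values` are log2 units, `FALSE` for
#'   raw intensities.
#' @return An object of class `expr_matrix` with elements `values`,
#'   `detected`, `log2`.
#' @examples
#' m <- matrix(2^rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' expr_matrix(m)
#' @export
expr_matrix <- function(values, detected = NULL, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .fail("'values' must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    .fail("'values' must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(gid)) {
    .fail("duplicate gene id(s): %s",
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    .fail("duplicate sample id(s): %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (isTRUE(log2) && any(!is.finite(values))) {
    .fail("log-space values must all be finite")
  }
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!is.logical(detected) || !identical(dim(detected), dim(values))) {
    .fail("'detected' must be a logical matrix of the same shape as 'values'")
  }
  dimnames(detected) <- dimnames(values)
  structure(list(values = values, detected = detected, log2 = isTRUE(log2)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2 units" else "raw intensities"))
  cat(sprintf("  detected: %.1f%% of entries above background\n",
              100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

# row-subset keeping mask and flag
.subset_genes <- function(x, keep) {
  expr_matrix(x$values[keep, , drop = FALSE],
              x$detected[keep, , drop = FALSE], log2 = x$log2)
}

# split sample ids by quality label; errors if a group is empty
.quality_groups <- function(phenotypes, sample_ids) {
  if (!all(c("sample_id", "label") %in% names(phenotypes))) {
    .fail("'phenotypes' must have columns 'sample_id' and 'label'")
  }
  ph <- phenotypes[match(sample_ids, phenotypes$sample_id), ]
  good <- sample_ids[!is.na(ph$label) & ph$label == "good"]
  bad  <- sample_ids[!is.na(ph$label) & ph$label == "bad"]
  if (length(good) == 0) .fail("no samples labeled 'good'")
  if (length(bad) == 0) .fail("no samples labeled 'bad'")
  list(good = good, bad = bad)
}

# survival vector aligned to the matrix columns
.aligned_survival <- function(phenotypes, sample_ids) {
  if (!all(c("sample_id", "survival") %in% names(phenotypes))) {
    .fail("'phenotypes' must have columns 'sample_id' and 'survival'")
  }
  i <- match(sample_ids, phenotypes$sample_id)
  if (anyNA(i)) {
    .fail("phenotypes missing for sample(s): %s",
          paste(sample_ids[is.na(i)], collapse = ", "))
  }
  phenotypes$survival[i]
}
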