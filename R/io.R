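# Plain-text I/O: expression matrices as TSV (first column gene id, header
# row of sample ids), GEO-style series-matrix files, parallel 0/1 detection
# masks, phenotype tables, and ground-truth key-value files.

# parse a TSV expression table from a character vector of lines, reporting
# 1-based line numbers (offset accounts for skipped header lines)
.parse_expr_lines <- function(lines, offset = 0) {
  if (length(lines) < 2) .fail("expression table needs a header and data")
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  sids <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  gids <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(sids))
  for (i in seq_along(rows)) {
    f <- strip(rows[[i]])
    line_no <- offset + i + 1
    if (length(f) != length(sids) + 1) {
      .fail("line %d: expected %d fields, found %d",
            line_no, length(sids) + 1, length(f))
    }
    gids[i] <- f[1]
    x <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(x)) {
      .fail("line %d: non-numeric or missing value for gene '%s'",
            line_no, f[1])
    }
    vals[i, ] <- x
  }
  dup <- gids[duplicated(gids)]
  if (length(dup) > 0) {
    .fail("duplicate gene id '%s' (line %d)", dup[1],
          offset + which(gids == dup[1])[2] + 1)
  }
  dimnames(vals) <- list(gids, sids)
  vals
}

#' Read an expression matrix from TSV or a GEO-style series-matrix file
#'
#' TSV dialect: header row of sample ids, first column gene ids, tab
#' separated numeric values. Series-matrix dialect: metadata lines starting
#' with `!` are skipped and the table is read between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' Duplicate ids, ragged rows and non-numeric cells are parse errors naming
#' the offending line.
#'
#' @param path File path.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param log2 Whether the stored values are log2 units (default `FALSE`).
#' @param detected_path Optional path of a parallel 0/1 detection-mask TSV.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix"),
                            log2 = FALSE, detected_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .fail("file not found: %s", path)
  lines <- readLines(path)
  if (format == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
      .fail("series-matrix table markers not found in %s", path)
    }
    offset <- beg
    lines <- lines[(beg + 1):(end - 1)]
  } else {
    offset <- 0
    lines <- lines[nzchar(lines)]
  }
  vals <- .parse_expr_lines(lines, offset)
  detected <- NULL
  if (!is.null(detected_path)) {
    dm <- .parse_expr_lines(readLines(detected_path))
    if (!identical(dimnames(dm), dimnames(vals))) {
      .fail("detection mask ids do not match the expression matrix")
    }
    detected <- dm > 0
  }
  expr_matrix(vals, detected, log2 = log2)
}

#' Write an expression matrix (and detection mask) as TSV
#'
#' @param x An [expr_matrix()].
#' @param path Output TSV path for the values.
#' @param detected_path Optional path for the parallel 0/1 detection mask.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, detected_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  write_tab <- function(m, p) {
    # 17 significant digits so numeric round trips are bit-exact
    ch <- matrix(formatC(m, digits = 17, format = "g"), nrow(m),
                 dimnames = dimnames(m))
    df <- data.frame(gene_id = rownames(m), ch, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tab(x$values, path)
  if (!is.null(detected_path)) {
    write_tab(x$detected + 0L, detected_path)
  }
  invisible(path)
}

#' Read a phenotype table (sample_id, survival, optional label) from TSV
#' @param path File path.
#' @return data.frame with `sample_id`, `survival` and, when present,
#'   `label`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "survival") %in% names(ph))) {
    .fail("phenotype table must have columns 'sample_id' and 'survival'")
  }
  if (anyDuplicated(ph$sample_id)) .fail("duplicate sample id(s) in %s", path)
  ph
}

#' Write a phenotype table as TSV
#' @param phenotypes data.frame with `sample_id`, `survival`, optional
#'   `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset (matrix, mask, phenotypes, ground truth)
#'
#' Emits `matrix.tsv`, `detected.tsv`, `phenotypes.tsv` and a plain-text
#' `truth.txt` key-value file into `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "matrix.tsv"),
                   file.path(dir, "detected.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  tr <- dataset$truth
  lines <- c(
    paste0("signal_gene_ids=", paste(tr$signal_gene_ids, collapse = ";")),
    paste0("effect_weights=", paste(tr$effect_weights, collapse = ";")),
    paste0("absent_gene_ids=", paste(tr$absent_gene_ids, collapse = ";")),
    paste0("duplicate_blocks=",
           paste(vapply(tr$duplicate_blocks, paste, "", collapse = ","),
                 collapse = ";")))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
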