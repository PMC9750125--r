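#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects tab-separated text with a header row of sample identifiers and the
#' first column holding gene identifiers. Values must be numeric and
#' nonnegative. Duplicate gene identifiers are allowed on read (splice
#' isoforms are collapsed later by [collapse_duplicates()]); duplicate sample
#' identifiers are an error.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  read_matrix_tsv(path, nonnegative = TRUE)
}

read_matrix_tsv <- function(path, nonnegative = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) abort("no data rows")
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) < 1L) abort("header row has no sample identifiers")
  dup <- samples[duplicated(samples)]
  if (length(dup)) {
    abort(sprintf("duplicate sample identifiers: %s",
                  paste(unique(dup), collapse = ", ")))
  }

  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, name_repair = "minimal",
                    na = character()))
  if (nrow(df) == 0L) abort("no data rows")
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    p <- probs[1, ]  # `row` is the file line number
    abort(sprintf("ragged or malformed row at line %d: expected %s, got %s",
                  p$row, p$expected, p$actual))
  }

  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-numeric value '%s' at data row %d (column '%s')",
                  vals[bad[1, 1], bad[1, 2]], bad[1, 1], samples[bad[1, 2]]))
  }
  if (nonnegative) {
    neg <- which(num < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L) {
      abort(sprintf("negative value at data row %d (column '%s'); expression must be >= 0",
                    neg[1, 1], samples[neg[1, 2]]))
    }
  }
  dimnames(num) <- list(genes, samples)
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: the round trip reproduces values to full
#' double precision (written with 15 significant digits).
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    abort("`m` must be a matrix with gene rownames and sample colnames.")
  }
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column gene length table
#'
#' TSV with columns gene identifier and representative transcript length in
#' base pairs (one transcript per gene, typically the longest).
#'
#' @param path Path to a TSV file (header optional; detected).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2L) abort("gene length table needs two columns: gene, length")
  # drop a header row if the second field is not numeric
  if (is.na(suppressWarnings(as.numeric(df[[2]][1])))) df <- df[-1, ]
  if (nrow(df) == 0L) abort("no data rows in gene length table")
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len)) {
    abort(sprintf("non-numeric length at data row %d", which(is.na(len))[1]))
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  stats::setNames(len, df[[1]])
}

#' Read a clock gene set (one identifier per line)
#'
#' @param path Text file with one gene identifier per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return Character vector of gene identifiers.
#' @export
read_clock_genes <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) abort("clock gene set is empty")
  if (anyDuplicated(x)) abort("clock gene set contains duplicates")
  x
}

#' Read or write a reference clock-gene correlation matrix
#'
#' The reference is a symmetric correlation matrix of the clock gene set
#' (values in \[-1, 1\], unit diagonal), stored as TSV with gene identifiers
#' in both the header row and the first column.
#'
#' @param path Path to a TSV file.
#' @return `read_reference()`: a validated square numeric matrix with
#'   dimnames. `write_reference()`: `path`, invisibly.
#' @export
read_reference <- function(path) {
  m <- read_matrix_tsv(path, nonnegative = FALSE)
  validate_reference(m)
  m
}

#' @rdname read_reference
#' @param ref Square symmetric correlation matrix with gene dimnames.
#' @export
write_reference <- function(ref, path) {
  validate_reference(ref)
  write_expression(ref, path)
}

#' Validate a reference correlation matrix
#'
#' Checks squareness, matching dimnames, symmetry (to 1e-12), values in
#' \[-1, 1\] and a unit diagonal.
#'
#' @param ref Matrix to validate.
#' @return `ref`, invisibly (diagonal coerced to exactly 1).
#' @export
validate_reference <- function(ref) {
  if (!is.matrix(ref) || nrow(ref) != ncol(ref)) {
    abort("reference must be a square matrix")
  }
  if (is.null(rownames(ref)) || !identical(rownames(ref), colnames(ref))) {
    abort("reference row and column gene identifiers must match")
  }
  if (max(abs(ref - t(ref))) > 1e-12) abort("reference matrix is not symmetric")
  if (any(abs(ref) > 1 + 1e-12)) abort("reference entries must lie in [-1, 1]")
  if (max(abs(diag(ref) - 1)) > 1e-8) abort("reference diagonal must be 1")
  diag(ref) <- 1
  invisible(ref)
}

#' Write screen scores to TSV and ranked .rnk output
#'
#' `write_scores()` writes the full per-gene score table.
#' `write_rnk()` writes a two-column, header-less ranked gene list
#' (gene, score, descending), the convention consumed by pre-ranked
#' enrichment tools.
#'
#' @param scores An `ltm_screen` object or its score tibble.
#' @param path Output path.
#' @param value Column to rank by for `write_rnk()` (default `ltm_abs`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  tbl <- if (inherits(scores, "ltm_screen")) scores$scores else scores
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
write_rnk <- function(scores, path, value = "ltm_abs") {
  tbl <- if (inherits(scores, "ltm_screen")) scores$scores else scores
  if (!value %in% names(tbl)) abort(sprintf("column '%s' not found", value))
  out <- tbl[!is.na(tbl[[value]]), c("gene", value)]
  out <- out[order(-out[[value]]), ]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
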