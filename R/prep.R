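#' Convert raw counts to TPM
#'
#' Per sample, each gene's count is divided by its representative transcript
#' length (base pairs) to a rate, and rates are rescaled so the column sums
#' to one million: `TPM_g = (count_g / length_g) / sum_h(count_h / length_h)
#' * 1e6`. A single representative length per gene is used (conventionally
#' the longest transcript); no effective-length correction is applied.
#'
#' @param counts Nonnegative gene-by-sample count matrix with dimnames.
#' @param lengths Named numeric vector of transcript lengths (bp), or a
#'   two-column data frame (gene, length). Every gene in `counts` must have
#'   a positive length.
#' @return TPM matrix of the same shape; all-zero sample columns stay zero
#'   and trigger a warning.
#' @examples
#' cts <- matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' tpm_from_counts(cts, c(A = 1000, B = 2000))
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.")
  }
  if (is.null(rownames(counts))) abort("`counts` must have gene rownames.")
  if (any(counts < 0)) abort("negative counts are not allowed")
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(as.numeric(lengths[[2]]), lengths[[1]])
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    abort(sprintf("no length supplied for gene(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) abort("gene lengths must be positive")

  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot <= 0
  if (any(zero)) {
    warn(sprintf("%d all-zero sample column(s) left as zero: %s",
                 sum(zero), paste(colnames(counts)[zero], collapse = ", ")))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample column onto the identical value distribution: the
#' value at rank r becomes the mean, across columns, of each column's r-th
#' smallest value. Tied values within a column receive the mean of the
#' normalized values at their tied ranks, so the result is deterministic and
#' invariant to sample-order permutation. Applying the operation twice gives
#' the same result as applying it once.
#'
#' @param m Nonnegative gene-by-sample matrix with dimnames.
#' @return Normalized matrix, same dimnames. A single-sample matrix is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  assert_expression(m)
  n <- ncol(m)
  if (n < 2L) {
    warn("quantile normalization needs >= 2 samples; returning input unchanged")
    return(m)
  }
  # per-rank means over column-sorted values
  sorted <- apply(m, 2, sort, method = "radix")
  target <- rowMeans(sorted)
  out <- m
  for (j in seq_len(n)) {
    col <- m[, j]
    v <- numeric(length(col))
    v[order(col, method = "radix")] <- target
    # ties: average the target values assigned within each tie group
    out[, j] <- stats::ave(v, col, FUN = mean)
  }
  out
}

#' Collapse duplicate gene rows
#'
#' Merges rows sharing a gene identifier (e.g. splice isoforms quantified
#' separately) into a single row per gene.
#'
#' @param m Gene-by-sample matrix; rownames may repeat.
#' @param rule `"mean"` (element-wise mean, default), `"sum"` (element-wise
#'   sum), or `"max-mean-row"` (keep the single row with the highest mean).
#' @return Matrix with one row per unique gene identifier, in first-occurrence
#'   order.
#' @export
collapse_duplicates <- function(m, rule = c("mean", "sum", "max-mean-row")) {
  rule <- match.arg(rule)
  if (!is.matrix(m) || is.null(rownames(m))) {
    abort("`m` must be a matrix with gene rownames.")
  }
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  keep_order <- unique(ids)
  out <- switch(rule,
    sum  = rowsum(m, group = ids, reorder = FALSE),
    mean = rowsum(m, group = ids, reorder = FALSE) /
             as.vector(table(factor(ids, levels = keep_order))),
    `max-mean-row` = {
      mu <- rowMeans(m)
      pick <- vapply(split(seq_along(ids), factor(ids, levels = keep_order)),
                     function(i) i[which.max(mu[i])], integer(1))
      m[pick, , drop = FALSE]
    })
  rownames(out) <- keep_order
  out
}

#' Remove genes with low expression across samples
#'
#' Retains genes whose value exceeds `min_expression` in at least
#' `min_expressed_fraction` of samples. Defaults follow a common bulk
#' RNA-seq convention (TPM > 1 in at least 25% of samples).
#'
#' @param m Gene-by-sample matrix.
#' @param min_expression Expression threshold a value must exceed (strictly).
#' @param min_expressed_fraction Required fraction of samples above threshold.
#' @return Filtered matrix; reports the number of genes removed. Errors if
#'   no gene survives.
#' @export
filter_low_expression <- function(m, min_expression = 1,
                                  min_expressed_fraction = 0.25) {
  assert_expression(m)
  assert_scalar_number(min_expression, "min_expression", lower = 0)
  assert_scalar_number(min_expressed_fraction, "min_expressed_fraction", 0, 1)
  frac <- rowMeans(m > min_expression)
  keep <- frac >= min_expressed_fraction
  if (!any(keep)) {
    abort(paste0("all genes removed by the low-expression filter; ",
                 "relax `min_expression` or `min_expressed_fraction`"))
  }
  removed <- sum(!keep)
  if (removed > 0) {
    inform(sprintf("filter_low_expression: removed %d of %d genes",
                   removed, nrow(m)))
  }
  m[keep, , drop = FALSE]
}

#' Blunt (winsorize) extreme expression values per gene
#'
#' Per gene row, values below the `winsor_lower` quantile are raised to that
#' quantile and values above the `winsor_upper` quantile are lowered to it.
#' Quantiles use the inverse-ECDF definition (type 1), so clamp values are
#' always observed data points. With fractions (0, 1) the matrix is returned
#' unchanged.
#'
#' @param m Gene-by-sample matrix.
#' @param winsor_lower,winsor_upper Tail fractions, `0 <= lower < upper <= 1`.
#'   Defaults 0.025 / 0.975.
#' @return Blunted matrix of the same shape.
#' @export
blunt_outliers <- function(m, winsor_lower = 0.025, winsor_upper = 0.975) {
  assert_expression(m)
  assert_scalar_number(winsor_lower, "winsor_lower", 0, 1)
  assert_scalar_number(winsor_upper, "winsor_upper", 0, 1)
  if (winsor_lower >= winsor_upper) {
    abort("`winsor_lower` must be strictly below `winsor_upper`")
  }
  if (winsor_lower == 0 && winsor_upper == 1) return(m)
  lo <- apply(m, 1, quantile, probs = winsor_lower, type = 1, names = FALSE)
  hi <- apply(m, 1, quantile, probs = winsor_upper, type = 1, names = FALSE)
  out <- pmin(pmax(m, lo), hi)  # lo/hi recycle down columns of the G x S matrix
  dimnames(out) <- dimnames(m)
  out
}

#' Prepare an expression matrix for screening
#'
#' Convenience pipeline over the individual preparation steps, applied in
#' this order: collapse duplicate gene rows, optional TPM conversion (when
#' `lengths` is supplied and `m` holds counts), quantile normalization,
#' low-expression filtering, and outlier blunting. Every step is optional
#' and individually available.
#'
#' @param m Gene-by-sample matrix (counts if `lengths` given, else TPM-like).
#' @param lengths Optional named length vector; triggers TPM conversion.
#' @param collapse_rule Passed to [collapse_duplicates()].
#' @param do_quantile_normalize Apply [quantile_normalize()]? Default TRUE.
#' @param min_expression,min_expressed_fraction Passed to
#'   [filter_low_expression()]; set `min_expressed_fraction = 0` to disable.
#' @param winsor_lower,winsor_upper Passed to [blunt_outliers()]; use
#'   `c(0, 1)` to disable.
#' @return Prepared matrix.
#' @export
ltm_prep <- function(m, lengths = NULL, collapse_rule = "mean",
                     do_quantile_normalize = TRUE,
                     min_expression = 1, min_expressed_fraction = 0.25,
                     winsor_lower = 0.025, winsor_upper = 0.975) {
  m <- collapse_duplicates(m, collapse_rule)
  if (!is.null(lengths)) m <- tpm_from_counts(m, lengths)
  if (do_quantile_normalize) m <- quantile_normalize(m)
  if (min_expressed_fraction > 0) {
    m <- filter_low_expression(m, min_expression, min_expressed_fraction)
  }
  if (!(winsor_lower == 0 && winsor_upper == 1)) {
    m <- blunt_outliers(m, winsor_lower, winsor_upper)
  }
  m
}
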