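#' Default clock and clock-associated gene set
#'
#' The 17 core clock and clock-associated genes conventionally used to probe
#' clock network state in mammalian expression data, with approximate mouse
#' peak expression times (circadian hours) and the relative amplitudes and
#' baselines the synthetic generator uses. The set is an editable input, not
#' a constant: pass any gene list to the screen functions.
#'
#' @return Tibble with columns `gene`, `peak_hours`, `amplitude`, `baseline`.
#' @export
clock_gene_defaults <- function() {
  tibble::tribble(
    ~gene,    ~peak_hours, ~amplitude, ~baseline,
    "ARNTL",  22.0,        24,         50,
    "NPAS2",  22.5,        18,         50,
    "CLOCK",  23.0,        10,         50,
    "NFIL3",  22.5,        14,         50,
    "CRY1",   18.0,        16,         50,
    "CRY2",   14.5,        12,         50,
    "PER1",   11.0,        22,         50,
    "PER2",   13.5,        20,         50,
    "PER3",   11.5,        24,         50,
    "NR1D1",   5.0,        26,         50,
    "NR1D2",   7.0,        22,         50,
    "RORA",   17.5,        10,         50,
    "RORB",   20.0,        12,         50,
    "RORC",   16.5,        14,         50,
    "DBP",    10.0,        26,         50,
    "TEF",    10.5,        18,         50,
    "HLF",    11.0,        16,         50
  )
}

#' Normalized coefficient of variation (nCV) of selected genes
#'
#' A gene's coefficient of variation (sd/mean over samples) divided by the
#' mean coefficient of variation of all genes in the matrix. The denominator
#' is taken over every gene in `m` with positive mean (a zero-mean gene has
#' no defined CV), not just the requested set. Genes with zero mean or zero
#' sd get nCV 0 and are flagged. nCV is invariant to positive rescaling of
#' the whole matrix and serves as a timestamp-free proxy for relative
#' oscillation amplitude.
#'
#' @param m Gene-by-sample matrix (>= 2 samples).
#' @param genes Character vector of gene identifiers to report.
#' @return Tibble with columns `gene`, `cv`, `ncv`, `flagged` (TRUE where
#'   nCV was forced to 0). Requested genes absent from `m` are dropped with
#'   a warning; if all are absent, an error.
#' @export
ncv <- function(m, genes) {
  assert_expression(m)
  if (ncol(m) < 2L) abort("nCV needs >= 2 samples")
  genes <- as.character(genes)
  present <- genes %in% rownames(m)
  if (!any(present)) abort("none of the requested genes are present in `m`")
  if (!all(present)) {
    warn(sprintf("excluding %d gene(s) absent from the matrix: %s",
                 sum(!present), paste(genes[!present], collapse = ", ")))
  }
  genes <- genes[present]

  st <- row_stats(m)
  cv_all <- ifelse(st$mean > 0, st$sd / st$mean, NA_real_)
  denom <- mean(cv_all, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) {
    abort("mean CV of the matrix is not positive; cannot normalize")
  }
  idx <- match(genes, rownames(m))
  cv_g <- cv_all[idx]
  flagged <- !is.finite(cv_g) | cv_g == 0
  ncv_g <- ifelse(flagged, 0, cv_g / denom)
  tibble::tibble(gene = genes, cv = unname(ifelse(is.finite(cv_g), cv_g, 0)),
                 ncv = unname(ncv_g), flagged = unname(flagged))
}

#' Clock-gene expression correlation matrix
#'
#' Pairwise correlation of the selected genes' expression across samples,
#' the "query" matrix compared against the reference by [mantel_zstat()].
#' A gene constant across the samples yields correlation 0 with all others
#' (keeping dimensions aligned with the reference) and is flagged.
#'
#' @param m Gene-by-sample matrix (>= 3 samples).
#' @param genes Clock gene identifiers (>= 3 present in `m`).
#' @param method `"spearman"` (default; robust to monotone distortion across
#'   population samples) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant_genes` lists flagged genes.
#' @export
clock_correlation <- function(m, genes, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_expression(m)
  genes <- intersect(as.character(genes), rownames(m))
  if (length(genes) < 3L) abort("need >= 3 clock genes present in the matrix")
  if (ncol(m) < 3L) abort("need >= 3 samples for a correlation matrix")
  sub <- m[genes, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(sub), method = method))
  const <- genes[apply(sub, 1, function(x) max(x) == min(x))]
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "constant_genes") <- const
  cc
}

#' Mantel cross-product similarity of two correlation matrices
#'
#' The raw Mantel statistic: the sum over unordered gene pairs (strictly
#' lower triangle) of the product of corresponding entries of the query and
#' reference matrices. Larger values mean the query's pairwise correlation
#' pattern is more similar to the reference. No permutation standardization
#' is applied; only the relative ordering across quantile groups feeds the
#' downstream correlations.
#'
#' @param query Symmetric square matrix (e.g. from [clock_correlation()]).
#' @param reference Symmetric square matrix of the same dimension and gene
#'   order (dimnames, when present on both, must match).
#' @return Scalar similarity statistic.
#' @export
mantel_zstat <- function(query, reference) {
  if (!is.matrix(query) || !is.matrix(reference) ||
      nrow(query) != ncol(query) || nrow(reference) != ncol(reference)) {
    abort("`query` and `reference` must be square matrices")
  }
  if (!all(dim(query) == dim(reference))) {
    abort(sprintf("dimension mismatch: query is %dx%d, reference is %dx%d",
                  nrow(query), ncol(query), nrow(reference), ncol(reference)))
  }
  qn <- rownames(query); rn <- rownames(reference)
  if (!is.null(qn) && !is.null(rn) && !identical(qn, rn)) {
    bad <- which(qn != rn)
    abort(sprintf("gene order mismatch at position(s) %s: query has %s, reference has %s",
                  paste(utils::head(bad, 5), collapse = ","),
                  paste(utils::head(qn[bad], 5), collapse = ","),
                  paste(utils::head(rn[bad], 5), collapse = ",")))
  }
  lt <- lower.tri(query)
  sum(query[lt] * reference[lt])
}

#' Clock strength of a sample set
#'
#' Bundles the two clock-strength measures for one group of samples: the
#' mean nCV of the clock genes present (amplitude proxy) and the Mantel
#' cross-product similarity of their correlation matrix to the reference
#' (phase-relationship conservation). When clock genes are missing from the
#' matrix, both the query and the reference are subset to the shared genes
#' before the Mantel statistic.
#'
#' @inheritParams clock_correlation
#' @param reference Reference correlation matrix (see [validate_reference()]).
#' @return Object of class `clock_strength`: list with `mean_ncv`, `zstat`,
#'   `n_genes_used`, `flagged_genes`.
#' @export
clock_strength <- function(m, genes, reference,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  validate_reference(reference)
  genes <- as.character(genes)
  shared <- intersect(intersect(genes, rownames(m)), rownames(reference))
  if (length(shared) < 3L) {
    abort("need >= 3 clock genes shared between matrix, gene set and reference")
  }
  nc <- ncv(m, shared)
  q <- clock_correlation(m, shared, method)
  ref_sub <- reference[shared, shared, drop = FALSE]
  z <- mantel_zstat(q[shared, shared, drop = FALSE], ref_sub)
  structure(list(mean_ncv = mean(nc$ncv), zstat = z,
                 n_genes_used = length(shared),
                 flagged_genes = nc$gene[nc$flagged]),
            class = "clock_strength")
}

#' @export
print.clock_strength <- function(x, ...) {
  cat(sprintf("<clock_strength> mean nCV = %.4f, Mantel zstat = %.4f (%d genes)\n",
              x$mean_ncv, x$zstat, x$n_genes_used))
  invisible(x)
}
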