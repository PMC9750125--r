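#' Quantile-group sizes for n samples in k groups
#'
#' Group boundaries sit at cumulative index `ceiling(i * n / k)`, so sizes
#' differ by at most one and sum to n. For n = 298, k = 4 this gives
#' (75, 74, 75, 74).
#'
#' @param n Number of samples.
#' @param k Number of groups.
#' @return Integer vector of k group sizes.
#' @export
partition_sizes <- function(n, k) {
  bounds <- ceiling(seq_len(k) * n / k)
  as.integer(diff(c(0L, bounds)))
}

#' Partition samples into expression quantile groups
#'
#' Samples are ranked ascending by the driver gene's expression (stable on
#' input order for ties) and cut into k contiguous groups Q1..Qk; Q1 holds
#' the lowest-expressing samples. Boundaries follow [partition_sizes()].
#'
#' @param x Numeric vector of driver expression, one value per sample
#'   (names preserved).
#' @param k Number of groups (>= 2); requires `length(x) >= 2 * k`.
#' @return Integer vector of group indices (1..k) aligned to the input
#'   order, with attribute `sizes`.
#' @export
partition_samples <- function(x, k) {
  n <- length(x)
  if (k < 2L) abort("`k` must be >= 2")
  if (n < 2L * k) {
    abort(sprintf("need at least 2*k = %d samples, got %d", 2L * k, n))
  }
  sizes <- partition_sizes(n, k)
  ord <- order(x, method = "radix")  # stable for ties
  grp <- integer(n)
  grp[ord] <- rep.int(seq_len(k), sizes)
  names(grp) <- names(x)
  attr(grp, "sizes") <- sizes
  grp
}

#' Per-group clock strength along one gene's expression gradient
#'
#' The "heat" step of the screen for a single driver gene: samples are
#' partitioned into k quantile groups by the driver's expression, and each
#' group's clock strength (mean clock-gene nCV and Mantel zstat against the
#' reference) is computed alongside its mean driver expression.
#'
#' @param m Prepared gene-by-sample matrix.
#' @param driver Gene identifier to stratify by (must be a row of `m`).
#' @param k Number of quantile groups.
#' @param clock_genes Clock gene identifiers.
#' @param reference Reference correlation matrix.
#' @param method Correlation flavor for the clock matrix
#'   (`"spearman"`/`"pearson"`).
#' @return Tibble of class `ltm_heat`, one row per group Q1..Qk: `group`,
#'   `n_samples`, `mean_driver`, `mean_ncv`, `zstat`, `n_genes_used`.
#'   Attributes: `driver`, `k`, `degenerate` (TRUE when the driver is
#'   constant so the partition is an input-order slicing).
#' @export
ltm_heat <- function(m, driver, k = 4, clock_genes, reference,
                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_expression(m)
  if (!driver %in% rownames(m)) {
    abort(sprintf("driver gene '%s' not found in the matrix", driver))
  }
  x <- m[driver, ]
  degenerate <- max(x) == min(x)
  if (degenerate) {
    warn(sprintf("driver '%s' is constant: degenerate partition (input-order slices)",
                 driver))
  }
  grp <- partition_samples(x, k)
  rows <- purrr::map(seq_len(k), function(g) {
    idx <- which(grp == g)
    cs <- clock_strength(m[, idx, drop = FALSE], clock_genes, reference, method)
    tibble::tibble(group = g, n_samples = length(idx),
                   mean_driver = mean(x[idx]),
                   mean_ncv = cs$mean_ncv, zstat = cs$zstat,
                   n_genes_used = cs$n_genes_used)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ltm_heat", class(out))
  attr(out, "driver") <- driver
  attr(out, "k") <- k
  attr(out, "degenerate") <- degenerate
  out
}

#' Correlate clock strength with driver expression across groups
#'
#' The "cook" step: over the k quantile groups, correlates group mean driver
#' expression with group mean clock nCV (giving R(nCV)) and with the group
#' Mantel zstat (giving R(zstat)). A correlation with zero variance on
#' either side is undefined and flagged (NA), never silently 0.
#'
#' @param groups An `ltm_heat` tibble (or any tibble with `mean_driver`,
#'   `mean_ncv`, `zstat`).
#' @param flavor Correlation flavor across groups; Pearson by default (the
#'   group summaries are few points on an approximately linear trend).
#' @return One-row tibble: `r_ncv`, `r_zstat`, `r_ncv_defined`,
#'   `r_zstat_defined`.
#' @export
ltm_cook <- function(groups, flavor = c("pearson", "spearman")) {
  flavor <- match.arg(flavor)
  ok <- stats::complete.cases(groups[, c("mean_driver", "mean_ncv", "zstat")])
  g <- groups[ok, ]
  if (nrow(g) < 3L) {
    return(tibble::tibble(r_ncv = NA_real_, r_zstat = NA_real_,
                          r_ncv_defined = FALSE, r_zstat_defined = FALSE))
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = flavor)
  }
  r1 <- safe_cor(g$mean_driver, g$mean_ncv)
  r2 <- safe_cor(g$mean_driver, g$zstat)
  tibble::tibble(r_ncv = r1, r_zstat = r2,
                 r_ncv_defined = !is.na(r1), r_zstat_defined = !is.na(r2))
}

#' Combine per-k correlations into LTMpre, LTMori and LTMabs
#'
#' The "dish" step for one gene. Per k-setting, LTMpre is the mean of R(nCV)
#' and R(zstat) (defined only when both are). LTMori averages the defined
#' LTMpre values over k-settings, and LTMabs is its absolute value. Sign
#' semantics: positive LTMori means samples expressing the gene more highly
#' have a stronger clock; negative means the opposite.
#'
#' @param per_k Tibble with one row per k-setting: columns `k`, `r_ncv`,
#'   `r_zstat` (NA where undefined).
#' @return One-row tibble: `ltm_ori`, `ltm_abs`, `n_k_used`, plus
#'   `ltm_pre_k<k>` columns.
#' @export
ltm_dish <- function(per_k) {
  pre <- (per_k$r_ncv + per_k$r_zstat) / 2
  defined <- !is.na(pre)
  ori <- if (any(defined)) mean(pre[defined]) else NA_real_
  out <- tibble::tibble(ltm_ori = ori, ltm_abs = abs(ori),
                        n_k_used = sum(defined))
  pre_cols <- stats::setNames(as.list(pre), paste0("ltm_pre_k", per_k$k))
  dplyr::bind_cols(tibble::as_tibble(pre_cols), out)
}

#' Pre-screen gene filter on quantile-group expression
#'
#' For each gene (using its own k-group partition), drops genes whose Q1
#' (lowest) group mean is below `min_q1_expression` or whose Q-k / Q1 mean
#' ratio is below `min_fold_change`. Genes flat across their expression
#' range carry no usable gradient for the screen.
#'
#' @param m Gene-by-sample matrix.
#' @param k Number of quantile groups used for the cut (default 4).
#' @param min_q1_expression Minimum Q1 group mean.
#' @param min_fold_change Minimum Qk/Q1 mean ratio (>= 1 is vacuous at 1
#'   since group means are non-decreasing by construction).
#' @return Character vector of retained gene identifiers.
#' @export
ltm_gene_filter <- function(m, k = 4, min_q1_expression = 0,
                            min_fold_change = 1) {
  assert_expression(m)
  assert_scalar_number(min_q1_expression, "min_q1_expression", lower = 0)
  assert_scalar_number(min_fold_change, "min_fold_change", lower = 0)
  n <- ncol(m)
  sizes <- partition_sizes(n, k)
  n1 <- sizes[1]; nk <- sizes[k]
  sorted <- apply(m, 1, sort, method = "radix")  # n x G
  q1 <- colMeans(sorted[seq_len(n1), , drop = FALSE])
  qk <- colMeans(sorted[(n - nk + 1):n, , drop = FALSE])
  fold <- ifelse(q1 > 0, qk / q1, ifelse(qk > 0, Inf, 1))
  keep <- q1 >= min_q1_expression & fold >= min_fold_change
  rownames(m)[keep]
}

#' Genome-wide screen for clock-coupled genes
#'
#' Runs the full per-gene screen: for every candidate gene and every k in
#' `k_settings`, samples are stratified by that gene's expression, per-group
#' clock strength is measured, and R(nCV)/R(zstat) correlations are taken
#' across groups; the dish step then yields per-gene LTMpre/LTMori/LTMabs.
#' Genes belonging to the clock set itself are screened like any other but
#' flagged (`is_clock_gene`), since stratifying by a strong cycler confounds
#' circadian phase with expression level and such scores may be unreliable.
#'
#' @param m Prepared gene-by-sample matrix.
#' @param clock_genes Clock gene identifiers (character vector or the tibble
#'   from [clock_gene_defaults()]).
#' @param reference Reference correlation matrix.
#' @param k_settings Integer vector of quantile-group counts (default
#'   `c(4, 7, 10)`).
#' @param candidates Genes to screen; default all genes in `m`.
#' @param method Correlation flavor for the per-group clock matrix
#'   (default `"spearman"`).
#' @param flavor Correlation flavor for R(nCV)/R(zstat) across groups
#'   (default `"pearson"`).
#' @param min_group_size Minimum samples per group at the largest k
#'   (default 25); lower it deliberately for small datasets.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (the modular
#'   [ltm_heat()]/[ltm_cook()] composition); both produce identical scores.
#' @return Object of class `ltm_screen`: list with `scores` (tibble: `gene`,
#'   per-k `r_ncv_k*`, `r_zstat_k*`, `ltm_pre_k*`, then `ltm_ori`,
#'   `ltm_abs`, `n_k_used`, `is_clock_gene`) and the screen parameters.
#' @export
ltm_screen <- function(m, clock_genes, reference, k_settings = c(4, 7, 10),
                       candidates = NULL, method = c("spearman", "pearson"),
                       flavor = c("pearson", "spearman"),
                       min_group_size = 25, engine = c("cpp", "r")) {
  method <- match.arg(method)
  flavor <- match.arg(flavor)
  engine <- match.arg(engine)
  assert_expression(m)
  if (is.data.frame(clock_genes)) clock_genes <- clock_genes$gene
  clock_genes <- as.character(clock_genes)
  validate_reference(reference)
  k_settings <- sort(unique(as.integer(k_settings)))
  if (any(k_settings < 2L)) abort("every k must be >= 2")
  n <- ncol(m)
  if (floor(n / max(k_settings)) < min_group_size) {
    abort(sprintf(paste0("smallest group would have %d samples at k = %d, ",
                         "below min_group_size = %d; reduce k or lower ",
                         "`min_group_size`"),
                  floor(n / max(k_settings)), max(k_settings), min_group_size))
  }
  candidates <- candidates %||% rownames(m)
  if (length(candidates) == 0L) abort("empty candidate gene set")
  missing <- setdiff(candidates, rownames(m))
  if (length(missing)) {
    abort(sprintf("candidate gene(s) not in matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  shared <- intersect(intersect(clock_genes, rownames(m)), rownames(reference))
  if (length(shared) < 3L) {
    abort("need >= 3 clock genes shared between matrix, gene set and reference")
  }
  ref_sub <- reference[shared, shared, drop = FALSE]

  if (engine == "cpp") {
    res <- cpp_ltm_screen(m, match(shared, rownames(m)) - 1L, ref_sub,
                          match(candidates, rownames(m)) - 1L,
                          k_settings, method == "spearman",
                          flavor == "spearman")
    r_ncv <- res$r_ncv
    r_zstat <- res$r_zstat
  } else {
    nk <- length(k_settings)
    r_ncv <- matrix(NA_real_, length(candidates), nk)
    r_zstat <- matrix(NA_real_, length(candidates), nk)
    for (i in seq_along(candidates)) {
      for (j in seq_len(nk)) {
        heat <- suppressWarnings(
          ltm_heat(m, candidates[i], k_settings[j], shared, ref_sub, method))
        cook <- ltm_cook(heat, flavor)
        r_ncv[i, j] <- cook$r_ncv
        r_zstat[i, j] <- cook$r_zstat
      }
    }
  }
  r_ncv[is.nan(r_ncv)] <- NA_real_
  r_zstat[is.nan(r_zstat)] <- NA_real_

  pre <- (r_ncv + r_zstat) / 2
  n_k_used <- rowSums(!is.na(pre))
  ori <- rowMeans(pre, na.rm = TRUE)
  ori[n_k_used == 0] <- NA_real_

  scores <- tibble::tibble(gene = candidates)
  for (j in seq_along(k_settings)) {
    scores[[paste0("r_ncv_k", k_settings[j])]] <- r_ncv[, j]
    scores[[paste0("r_zstat_k", k_settings[j])]] <- r_zstat[, j]
    scores[[paste0("ltm_pre_k", k_settings[j])]] <- pre[, j]
  }
  scores$ltm_ori <- ori
  scores$ltm_abs <- abs(ori)
  scores$n_k_used <- as.integer(n_k_used)
  scores$is_clock_gene <- candidates %in% clock_genes

  structure(list(scores = scores, k_settings = k_settings, method = method,
                 flavor = flavor, n_samples = n, n_genes = nrow(m),
                 clock_genes = shared),
            class = "ltm_screen")
}

#' @export
print.ltm_screen <- function(x, ...) {
  cat(sprintf("<ltm_screen> %d candidate genes, %d samples, k = {%s}\n",
              nrow(x$scores), x$n_samples,
              paste(x$k_settings, collapse = ", ")))
  top <- dplyr::arrange(x$scores, dplyr::desc(.data$ltm_abs))
  print(utils::head(dplyr::select(top, "gene", "ltm_ori", "ltm_abs"), 5))
  invisible(x)
}

#' Integrate screen scores across datasets
#'
#' For each gene present in at least `min_datasets` score tables, the
#' integrated LTMori is the mean of the per-dataset LTMori values and the
#' integrated LTMabs its absolute value. Opposite-signed associations in
#' different datasets therefore cancel, as intended: only directionally
#' consistent coupling survives integration.
#'
#' @param tables List (>= 2) of `ltm_screen` objects or score tibbles with
#'   columns `gene` and `ltm_ori`.
#' @param min_datasets Minimum datasets a gene must appear in with a defined
#'   LTMori (default: all of them).
#' @return Tibble: `gene`, `n_datasets`, `ltm_ori_integrated`,
#'   `ltm_abs_integrated`, sorted by descending integrated LTMabs.
#' @export
ltm_meta <- function(tables, min_datasets = NULL) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort("`tables` must be a list of >= 2 score tables")
  }
  min_datasets <- min_datasets %||% length(tables)
  tbls <- purrr::map(tables, function(t) {
    s <- if (inherits(t, "ltm_screen")) t$scores else t
    if (!all(c("gene", "ltm_ori") %in% names(s))) {
      abort("each table needs columns `gene` and `ltm_ori`")
    }
    s[!is.na(s$ltm_ori), c("gene", "ltm_ori")]
  })
  out <- dplyr::bind_rows(tbls, .id = "dataset") |>
    dplyr::summarise(n_datasets = dplyr::n(),
                     ltm_ori_integrated = mean(.data$ltm_ori),
                     .by = "gene") |>
    dplyr::filter(.data$n_datasets >= min_datasets) |>
    dplyr::mutate(ltm_abs_integrated = abs(.data$ltm_ori_integrated)) |>
    dplyr::arrange(dplyr::desc(.data$ltm_abs_integrated))
  if (nrow(out) == 0L) {
    abort(sprintf("no gene appears in >= %d datasets with a defined LTMori",
                  min_datasets))
  }
  out
}

#' Normalize LTMabs scores against a random-gene background
#'
#' Divides each target gene's LTMabs by the mean LTMabs of randomly sampled
#' gene sets: `n_rounds` rounds each draw (without replacement) as many
#' genes as there are targets, and the normalizer is the mean over rounds of
#' the round-mean LTMabs. Scores near 1 are background-like; scores above 1
#' indicate stronger-than-random coupling. Makes scores comparable across
#' datasets with different LTMabs scales.
#'
#' @param scores An `ltm_screen` object or score tibble with `gene`,
#'   `ltm_abs`.
#' @param target_genes Genes to report normalized scores for.
#' @param n_rounds Number of random rounds (default 1000).
#' @param seed Optional integer seed for reproducible sampling (RNG state is
#'   restored afterwards).
#' @return Tibble: `gene`, `ltm_abs`, `normalized`; attribute `background`
#'   holds the normalizing mean.
#' @export
background_normalize <- function(scores, target_genes, n_rounds = 1000,
                                 seed = NULL) {
  tbl <- if (inherits(scores, "ltm_screen")) scores$scores else scores
  if (n_rounds < 1L) abort("`n_rounds` must be >= 1")
  tbl <- tbl[!is.na(tbl$ltm_abs), ]
  target_genes <- as.character(target_genes)
  hit <- target_genes %in% tbl$gene
  if (!any(hit)) abort("none of the target genes have a defined LTMabs")
  if (!all(hit)) {
    warn(sprintf("dropping %d target gene(s) without a defined LTMabs",
                 sum(!hit)))
  }
  target_genes <- target_genes[hit]
  size <- length(target_genes)
  if (size > nrow(tbl)) abort("more target genes than scored genes")
  draw <- function() {
    mean(vapply(seq_len(n_rounds), function(i) {
      mean(tbl$ltm_abs[sample.int(nrow(tbl), size)])
    }, numeric(1)))
  }
  bg <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  idx <- match(target_genes, tbl$gene)
  out <- tibble::tibble(gene = target_genes, ltm_abs = tbl$ltm_abs[idx],
                        normalized = tbl$ltm_abs[idx] / bg)
  attr(out, "background") <- bg
  out
}
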