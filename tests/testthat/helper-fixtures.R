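# Shared fixtures and independent oracles. The oracles deliberately use the
# most literal formulation available (double loops, direct formulas) so they
# stay independent of the implementation paths they check.

make_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

rand_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    make_matrix(matrix(stats::rlnorm(n_genes * n_samples, 2, 0.5),
                       n_genes, n_samples))
  })
}

rand_symmetric <- function(d, seed = 1, unit_diag = TRUE) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(d * d, -1, 1), d, d)
    s <- (a + t(a)) / 2
    if (unit_diag) diag(s) <- 1
    rownames(s) <- colnames(s) <- sprintf("g%02d", seq_len(d))
    s
  })
}

# brute-force Mantel cross-product: explicit double loop over i < j
brute_mantel <- function(q, r) {
  z <- 0
  for (j in seq_len(ncol(q))) {
    for (i in seq_len(nrow(q))) {
      if (i > j) z <- z + q[i, j] * r[i, j]
    }
  }
  z
}

# direct nCV formula: per-gene CV over the mean CV of all positive-mean genes
brute_ncv <- function(m, genes) {
  cvs <- apply(m, 1, function(x) {
    if (mean(x) <= 0) NA_real_ else stats::sd(x) / mean(x)
  })
  denom <- mean(cvs, na.rm = TRUE)
  vapply(genes, function(g) {
    cv <- cvs[[g]]
    if (!is.finite(cv) || cv == 0) 0 else cv / denom
  }, numeric(1))
}

# small synthetic dataset for screen-level tests
small_sim <- function(seed = 1, n_samples = 120, n_genes = 150,
                      coupling_effect = 0.5) {
  generate_population(synthetic_config(n_samples = n_samples,
                                       n_genes = n_genes,
                                       coupling_effect = coupling_effect,
                                       seed = seed))
}

default_reference <- function(seed = 11) generate_reference(seed = seed)

`%||%` <- function(a, b) if (is.null(a)) b else a
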