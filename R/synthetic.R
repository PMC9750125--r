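#' Configuration for the synthetic population generator
#'
#' Defines a population of unordered samples with latent circadian phase and
#' latent clock strength, a clock gene set with fixed peak-phase
#' relationships, one planted "coupler" gene whose expression level
#' modulates clock strength, and structure-free decoy genes. Defaults mirror
#' the screen's reference conditions: 298 samples and 2000 genes (17 clock +
#' 1 coupler + 1982 decoys).
#'
#' @param n_samples Number of population samples (>= 20; default 298).
#' @param n_genes Total gene count including clock genes and the coupler
#'   (default 2000).
#' @param coupling_effect Slope linking the standardized coupler expression
#'   to latent clock strength on the softplus scale (default 0.5; 0 plants
#'   no coupling — the null).
#' @param strength_noise SD of the latent-strength noise on the softplus
#'   scale (default 0.15).
#' @param expression_noise_cv Measurement noise SD as a fraction of each
#'   clock gene's baseline (default 0.1).
#' @param decoy_noise_cv Decoy expression SD as a fraction of baseline
#'   (default 0.3).
#' @param clock_genes Tibble with `gene`, `peak_hours`, `amplitude`,
#'   `baseline` (default [clock_gene_defaults()]).
#' @param coupler_baseline,coupler_sd Mean and SD of the planted coupler's
#'   expression (defaults 100 and 30).
#' @param seed Optional integer seed; every generator call with the same
#'   config (seed included) is bit-identical.
#' @return Validated list of class `ltm_sim_config`.
#' @export
synthetic_config <- function(n_samples = 298, n_genes = 2000,
                             coupling_effect = 0.5, strength_noise = 0.15,
                             expression_noise_cv = 0.1, decoy_noise_cv = 0.3,
                             clock_genes = clock_gene_defaults(),
                             coupler_baseline = 100, coupler_sd = 30,
                             seed = NULL) {
  if (n_samples < 20) abort("`n_samples` must be >= 20")
  assert_scalar_number(strength_noise, "strength_noise", lower = 0)
  assert_scalar_number(expression_noise_cv, "expression_noise_cv", lower = 0)
  assert_scalar_number(decoy_noise_cv, "decoy_noise_cv", lower = 0)
  assert_scalar_number(coupling_effect, "coupling_effect")
  stopifnot(is.data.frame(clock_genes),
            all(c("gene", "peak_hours", "amplitude", "baseline") %in%
                  names(clock_genes)))
  if (any(clock_genes$amplitude < 0)) abort("amplitudes must be >= 0")
  if (n_genes < nrow(clock_genes) + 1L) {
    abort("`n_genes` must leave room for the clock set plus the coupler")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 coupling_effect = coupling_effect,
                 strength_noise = strength_noise,
                 expression_noise_cv = expression_noise_cv,
                 decoy_noise_cv = decoy_noise_cv,
                 clock_genes = clock_genes,
                 coupler_baseline = coupler_baseline,
                 coupler_sd = coupler_sd,
                 seed = seed),
            class = "ltm_sim_config")
}

#' Generate a synthetic population with planted clock coupling
#'
#' Each sample s carries a latent circadian phase (uniform on \[0, 24h)) and
#' a latent clock strength. The planted coupler's expression is Gaussian
#' around its baseline; strength is
#' `softplus(s0 + coupling_effect * z_s + noise)`, where `z_s` is the
#' standardized coupler expression and `s0` centres baseline strength at 1.
#' Clock gene g in sample s is
#' `baseline_g + strength_s * amplitude_g * cos(phase_s - peak_g) + noise`,
#' so strength scales oscillation amplitude — the quantity nCV proxies.
#' Decoys are independent of both phase and strength. Negative values are
#' floored at zero (and counted in the `n_floored` attribute of the truth).
#'
#' @param cfg An `ltm_sim_config` from [synthetic_config()].
#' @return List of class `ltm_sim`: `expression` (gene-by-sample matrix;
#'   clock genes, then `coupler`, then decoys), `truth` (list with per-sample
#'   tibble `samples` (`sample`, `phase`, `strength`, `coupler_expression`),
#'   `coupler`, `coupling_effect`).
#' @export
generate_population <- function(cfg) {
  if (!inherits(cfg, "ltm_sim_config")) abort("`cfg` must be an `ltm_sim_config`")
  run <- function() {
    n <- cfg$n_samples
    ck <- cfg$clock_genes
    ncg <- nrow(ck)
    n_decoy <- cfg$n_genes - ncg - 1L

    phase <- runif(n, 0, 2 * pi)
    x <- cfg$coupler_baseline + cfg$coupler_sd * rnorm(n)
    x <- pmax(x, 0)
    z <- if (stats::sd(x) > 0) as.vector(scale(x)) else rep(0, n)
    s0 <- log(expm1(1))  # softplus(s0) = 1
    strength <- softplus(s0 + cfg$coupling_effect * z +
                           rnorm(n, 0, cfg$strength_noise))

    peak <- ck$peak_hours / 24 * 2 * pi
    osc <- outer(ck$amplitude, strength) *
      cos(matrix(phase, ncg, n, byrow = TRUE) - peak)
    clock_expr <- ck$baseline + osc +
      matrix(rnorm(ncg * n, 0, cfg$expression_noise_cv * ck$baseline), ncg, n)

    decoy_base <- stats::rlnorm(n_decoy, meanlog = 3.5, sdlog = 1)
    decoy_expr <- decoy_base *
      (1 + matrix(rnorm(n_decoy * n, 0, cfg$decoy_noise_cv), n_decoy, n))

    expr <- rbind(clock_expr, matrix(x, 1, n), decoy_expr)
    n_floored <- sum(expr < 0)
    expr[expr < 0] <- 0
    rownames(expr) <- c(ck$gene, "coupler",
                        sprintf("decoy_%04d", seq_len(n_decoy)))
    colnames(expr) <- sprintf("s%03d", seq_len(n))

    truth <- list(samples = tibble::tibble(sample = colnames(expr),
                                           phase = phase,
                                           strength = strength,
                                           coupler_expression = x),
                  coupler = "coupler",
                  coupling_effect = cfg$coupling_effect)
    attr(truth, "n_floored") <- n_floored
    structure(list(expression = expr, truth = truth, config = cfg),
              class = "ltm_sim")
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

#' Generate a synthetic reference clock correlation matrix
#'
#' Simulates dense, low-noise cosine time courses with the configured
#' peak-phase relationships over whole circadian cycles and returns their
#' pairwise correlation matrix. In the noise-free limit with uniform
#' sampling of the cycle, the correlation of two genes peaking `delta`
#' radians apart is `cos(delta)`. This is a synthetic stand-in for a
#' reference derived from a timestamped circadian atlas.
#'
#' @param clock_genes Tibble with `gene` and `peak_hours`
#'   (default [clock_gene_defaults()]).
#' @param n_timepoints Timepoints per cycle (>= 8; default 48).
#' @param n_replicates Replicate cycles (default 2).
#' @param noise_sd SD of additive noise on the unit-amplitude cosines
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @return Symmetric correlation matrix with unit diagonal and gene
#'   dimnames, valid under [validate_reference()].
#' @export
generate_reference <- function(clock_genes = clock_gene_defaults(),
                               n_timepoints = 48, n_replicates = 2,
                               noise_sd = 0.05, seed = NULL) {
  if (nrow(clock_genes) < 2L) abort("need >= 2 clock genes")
  if (n_timepoints < 8L) abort("`n_timepoints` must be >= 8")
  run <- function() {
    peak <- clock_genes$peak_hours / 24 * 2 * pi
    t_rad <- rep(2 * pi * (seq_len(n_timepoints) - 1) / n_timepoints,
                 n_replicates)
    y <- cos(outer(-peak, t_rad, "+")) +
      matrix(rnorm(length(peak) * length(t_rad), 0, noise_sd),
             nrow = length(peak))
    cc <- stats::cor(t(y))
    dimnames(cc) <- list(clock_genes$gene, clock_genes$gene)
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    cc
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression matrix, the per-sample truth table and (optionally)
#' a reference matrix in the TSV formats the rest of the package consumes.
#'
#' @param sim An `ltm_sim` from [generate_population()].
#' @param dir Output directory (created if needed).
#' @param reference Optional reference matrix to write alongside.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, reference = NULL) {
  if (!inherits(sim, "ltm_sim")) abort("`sim` must be an `ltm_sim`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$truth$samples, paths[["truth"]], progress = FALSE)
  if (!is.null(reference)) {
    paths[["reference"]] <- file.path(dir, "reference.tsv")
    write_reference(reference, paths[["reference"]])
  }
  invisible(paths)
}
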