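---
title: "Screening population transcriptomes for clock-coupled genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening population transcriptomes for clock-coupled genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltmscreen)
```

## The problem

Time-series experiments have mapped which genes the circadian clock
controls, but population cohorts — biopsies, surgical resections, biobank
tissue — carry no timestamps, so they cannot be phase-ordered. What they do
carry is *natural variation*: hundreds of donors differ in how strongly
each gene is expressed, and, independently, in how robust their molecular
clock is. If a gene's expression level influences (or tracks) clock
robustness, then samples stratified by that gene's expression should show a
gradient of clock strength. `ltmscreen` turns that idea into a genome-wide
screen: an in-silico analogue of a knockdown screen, with the natural
expression range of each gene standing in for the perturbation.

## Clock strength without timestamps

Clock strength of a *group of samples* is quantified on two axes:

* **Amplitude — the normalized coefficient of variation (nCV).** In
  unordered samples, a gene oscillating with high amplitude spreads its
  values widely relative to its mean. We compute, per gene,
  $\mathrm{CV}_g = s_g / \bar{x}_g$ and normalize by the mean CV of all
  genes in the same sample group:
  $\mathrm{nCV}_g = \mathrm{CV}_g \big/ \overline{\mathrm{CV}}$.
  The denominator removes group-level technical spread, so nCV is invariant
  to rescaling the whole matrix. A strong clock gives clock genes high nCV.
* **Phase architecture — the Mantel cross-product.** Clock genes keep fixed
  phase relationships: genes peaking together correlate positively across
  samples, genes in antiphase negatively. The clock-gene correlation matrix
  of a sample group (Spearman by default) is compared to a reference
  correlation matrix by the raw Mantel statistic
  $z = \sum_{i<j} Q_{ij} R_{ij}$, the cross-product over unordered gene
  pairs. A strong, well-phased clock drives $z$ toward the reference's
  self-similarity $\sum_{i<j} R_{ij}^2$; a scrambled clock drives it to 0.
  We use the raw cross-product rather than a permutation-standardized
  version because only the *ordering* of $z$ across quantile groups enters
  the screen; standardization would add cost without changing ranks.

The clock gene set defaults to 17 core clock and clock-associated genes
(activators ARNTL/NPAS2/CLOCK, repressors PERs/CRYs/NR1Ds, the ROR and
PAR-bZIP families, NFIL3); it is an editable input, as is the reference
matrix.

## The screen

For each candidate gene ("driver") and each group count $k \in \{4, 7,
10\}$:

1. Samples are ranked by the driver's expression and cut into $k$
   contiguous quantile groups with boundaries at $\lceil i \cdot n / k
   \rceil$ — for $n = 298$, $k = 4$ this gives groups of 75/74/75/74.
   Ties keep input order (stable sort), so the partition is deterministic
   and invariant to any strictly increasing relabeling of the driver.
2. Each group yields (mean driver expression, mean clock nCV, Mantel $z$).
3. Across the $k$ groups, $R(\mathrm{nCV})$ and $R(z)$ are the Pearson
   correlations of the two clock measures with mean driver expression.
   Pearson is the default because the group summaries are a handful of
   points on an approximately linear trend; Spearman is available.
4. $\mathrm{LTMpre}_k = (R(\mathrm{nCV}) + R(z))/2$, averaging the two
   measures so that only genes consistent on both score highly.
5. $\mathrm{LTMori}$ is the mean of the defined $\mathrm{LTMpre}_k$ over
   k-settings and $\mathrm{LTMabs} = |\mathrm{LTMori}|$ is the final score
   in $[0, 1]$. A positive LTMori means high expression accompanies a
   strong clock; negative means the converse.

Zero-variance correlations (e.g. a constant driver) are *flagged as
undefined and excluded* from the LTMpre/LTMori averages rather than imputed
as 0, which would bias LTMabs toward 0; a gene with no defined k-setting is
reported as unscored. Multiple cohorts of the same tissue are integrated by
averaging per-dataset LTMori (`ltm_meta()`), so directionally inconsistent
associations cancel. For cross-dataset comparisons of gene families,
`background_normalize()` rescales LTMabs by the mean LTMabs of 1000
random gene draws of matching size.

Clock-set genes are screened like any other gene but flagged
(`is_clock_gene`): ranking samples by a strongly cycling gene confounds
circadian phase with expression level, so their own scores should be read
with caution. We report the flag rather than filtering, leaving the
decision to the analyst.

## Preparation defaults

`ltm_prep()` chains collapse → (optional TPM) → quantile normalization →
low-expression filter → winsorization. Choices where convention, not
theory, decides:

* Quantile normalization uses per-rank means with ties receiving the mean
  of their tied ranks' values — deterministic and permutation-invariant.
* Low-expression filter: value > 1 (TPM-like units) in ≥ 25% of samples, a
  common bulk RNA-seq convention; both knobs are exposed.
* Winsorization clamps each gene to its 2.5%/97.5% inverse-ECDF (type-1)
  quantiles. Type-1 quantiles guarantee the clamp values are observed data
  points, which keeps the operation idempotent on the clamped tails.
* Isoform collapse defaults to the element-wise mean; `sum` and
  `max-mean-row` are available.
* TPM conversion uses one representative (longest-transcript) length per
  gene with no effective-length correction.

The minimum group size defaults to 25 samples at the largest k: below
that, the per-group correlation matrices and CVs get noisy faster than the
extra quantile resolution helps.

## The synthetic model

The generator plants known structure so every stage is testable without
external data. Each sample carries a latent phase $\varphi_s \sim
U[0, 2\pi)$ and a latent clock strength; a designated coupler gene has
Gaussian expression (mean 100, sd 30), and strength is
$\sigma_s = \mathrm{softplus}(s_0 + \beta z_s + \varepsilon)$ with $z_s$
the standardized coupler level, $\beta$ the coupling effect (default 0.5,
0 for null studies), $\varepsilon \sim N(0, 0.15)$, and $s_0$ chosen so
baseline strength is 1. The softplus link keeps strength positive without
truncation and is monotone in the coupler. Clock gene $g$ is then

$$x_{gs} = b_g + \sigma_s A_g \cos(\varphi_s - \phi_g) + N(0, 0.1\,b_g),$$

so strength scales oscillation amplitude — exactly the quantity nCV
proxies — while the phase relationships $\phi_g$ (approximate mouse peak
times) are preserved, which is what the Mantel axis detects. Decoys are
independent of phase and strength, with lognormal baselines
($\mu_{\log} = 3.5$, $\sigma_{\log} = 1$) and 30% CV noise. Defaults
mirror the reference study geometry: 298 samples (whose 4-quantile
partition is 75/74/75/74) and 2000 genes.

The reference correlation matrix is generated from dense low-noise cosine
time courses over whole cycles; as noise → 0 the correlation of genes
peaking $\Delta$ apart approaches $\cos\Delta$. The shipped
`reference_correlation_synthetic.tsv` is exactly such a synthetic
stand-in — analyses of real data should substitute a reference derived
from a timestamped atlas of the matching tissue.

What the generator does **not** emulate: count-level sampling noise
(negative binomial library-size effects), batch structure, correlated
decoy blocks (co-regulated pathways), or cell-type mixture. Passing tests
therefore demonstrate that the statistics recover planted signal under
clean population variation, not that any particular real cohort is free of
confounding — in tissue data, cell composition or batch can dominate the
observed "clock strength" gradient, and the biological context must be
checked before interpreting a hit.

## Numerical and design notes

* The genome-wide loop runs in C++ (per-driver group accumulation, rank
  correlations, Mantel products); a pure-R path through
  `ltm_heat()`/`ltm_cook()` implements the identical pipeline and the test
  suite asserts the two agree to ~1e-10 — the R path is the readable
  specification, the C++ path the throughput engine.
* A clock gene constant within a group gets correlation 0 to all others
  (keeping the matrix aligned with the reference) and nCV 0, both flagged.
* The nCV denominator averages CVs of all genes with positive mean in the
  same quantile group; zero-mean genes have no defined CV and are excluded
  from the denominator (their own nCV is reported as 0).
* Determinism: every stochastic routine takes a seed and restores RNG
  state; equal config + seed gives bit-identical output.
* Problem sizes in the validation suite — a full 2000 × 298 screen for
  range invariants, 20 seeded replicates for planted-gene recovery, 50
  replicates at 400 genes for null calibration — were chosen as the
  smallest designs whose pass/fail verdicts are stable across reruns.
* Null calibration uses a randomized PIT of the planted gene's rank so the
  discrete uniform rank law maps exactly to $U[0,1]$ before the
  Kolmogorov–Smirnov check.

## Limitations

Scores are correlations: a top gene may drive the clock, be driven by it,
or share an upstream cause (including cell-type composition). The screen
cannot see period or phase variation, only strength. Strong cyclers are
phase-confounded as drivers (flagged, not removed). And with 4–10 group
summaries per correlation, individual $R$ values are noisy — the power of
the design comes from averaging two measures, several k-settings and,
where available, several datasets.
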