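#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a screen result into a long per-gene, per-k tibble
#'
#' @param x An `ltm_screen` object.
#' @param ... Unused.
#' @return Tibble with one row per gene and k-setting: `gene`, `k`,
#'   `r_ncv`, `r_zstat`, `ltm_pre`, plus the per-gene `ltm_ori`, `ltm_abs`.
#' @method tidy ltm_screen
#' @export
tidy.ltm_screen <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$scores,
    cols = tidyr::matches("^(r_ncv|r_zstat|ltm_pre)_k\\d+$"),
    names_to = c(".value", "k"),
    names_pattern = "^(r_ncv|r_zstat|ltm_pre)_k(\\d+)$")
  long$k <- as.integer(long$k)
  dplyr::select(long, "gene", "k", "r_ncv", "r_zstat", "ltm_pre",
                "ltm_ori", "ltm_abs", "is_clock_gene")
}

#' One-row summary of a screen
#'
#' @param x An `ltm_screen` object.
#' @param ... Unused.
#' @return One-row tibble: gene/sample counts, k-settings, score summary
#'   and the top-scoring gene.
#' @method glance ltm_screen
#' @export
glance.ltm_screen <- function(x, ...) {
  s <- x$scores
  top <- s$gene[which.max(s$ltm_abs)]
  tibble::tibble(n_candidates = nrow(s), n_genes = x$n_genes,
                 n_samples = x$n_samples,
                 k_settings = paste(x$k_settings, collapse = ","),
                 n_scored = sum(!is.na(s$ltm_abs)),
                 median_ltm_abs = stats::median(s$ltm_abs, na.rm = TRUE),
                 max_ltm_abs = max(s$ltm_abs, na.rm = TRUE),
                 top_gene = top)
}

#' Plot the LTMabs score distribution of a screen
#'
#' Histogram of per-gene LTMabs with clock-set genes overlaid as a rug;
#' an optional set of genes to highlight is marked with vertical lines.
#'
#' @param object An `ltm_screen` object.
#' @param highlight Optional gene identifiers to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ltm_screen
#' @export
autoplot.ltm_screen <- function(object, highlight = NULL, ...) {
  s <- object$scores[!is.na(object$scores$ltm_abs), ]
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$ltm_abs)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::geom_rug(data = s[s$is_clock_gene, ], colour = "steelblue") +
    ggplot2::labs(x = "LTMabs", y = "genes",
                  title = "Screen score distribution",
                  subtitle = "rug: clock-set genes") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    h <- s[s$gene %in% highlight, ]
    p <- p + ggplot2::geom_vline(data = h,
                                 ggplot2::aes(xintercept = .data$ltm_abs),
                                 colour = "firebrick", linetype = 2) +
      ggplot2::geom_text(data = h,
                         ggplot2::aes(x = .data$ltm_abs, y = Inf,
                                      label = .data$gene),
                         vjust = 1.5, hjust = -0.1, colour = "firebrick",
                         size = 3)
  }
  p
}

#' Plot per-group clock strength along a driver gene's gradient
#'
#' Shows the two clock-strength measures (mean clock nCV and Mantel zstat)
#' against group mean driver expression, one panel each — the trend whose
#' correlations become R(nCV) and R(zstat).
#'
#' @param object An `ltm_heat` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ltm_heat
#' @export
autoplot.ltm_heat <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("mean_ncv", "zstat"),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, c("mean_ncv", "zstat"),
                         c("mean clock nCV", "Mantel zstat"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_driver, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = sprintf("mean %s expression per quantile group",
                              attr(object, "driver") %||% "driver"),
                  y = "clock strength measure") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
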