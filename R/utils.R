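#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor quantile sd rnorm runif
#' @import Rcpp
#' @useDynLib ltmscreen, .registration = TRUE
NULL

# Row means and (n-1)-denominator standard deviations without apply() copies.
row_stats <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n < 2) {
    s <- rep(NA_real_, nrow(m))
  } else {
    s2 <- (rowSums(m * m) - n * mu^2) / (n - 1)
    s <- sqrt(pmax(s2, 0))
  }
  list(mean = mu, sd = s)
}

assert_expression <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric gene-by-sample matrix.", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyNA(m) || any(!is.finite(m))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(m < 0)) {
    abort(sprintf("`%s` contains negative values; expression must be >= 0.", arg))
  }
  invisible(m)
}

assert_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", arg, lower, upper))
  }
  invisible(x)
}

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  ifelse(x > 30, x, log1p(exp(x)))
}
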