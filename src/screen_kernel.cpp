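// Fast path for the genome-wide screen: for each candidate driver gene,
// stratify samples into quantile groups by that gene's expression, compute
// per-group clock strength (mean clock-gene nCV + Mantel cross-product of
// the clock correlation matrix against the reference), then correlate the
// group summaries with group mean driver expression. Mirrors the modular R
// path (ltm_heat/ltm_cook) exactly; equivalence is asserted in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// average-tie ranks, matching base R rank(ties.method = "average")
static arma::vec avg_ranks(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::stable_sort_index(x);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    double avg = 0.5 * (double)(i + j) + 1.0;  // mean of ranks i+1 .. j+1
    for (arma::uword t = i; t <= j; ++t) r(ord(t)) = avg;
    i = j + 1;
  }
  return r;
}

// Pearson correlation with NaN for zero variance on either side
static double pearson_or_nan(const arma::vec& a, const arma::vec& b) {
  const arma::uword n = a.n_elem;
  double ma = arma::mean(a), mb = arma::mean(b);
  arma::vec ca = a - ma, cb = b - mb;
  double na2 = arma::dot(ca, ca), nb2 = arma::dot(cb, cb);
  if (n < 3 || na2 <= 0.0 || nb2 <= 0.0) return arma::datum::nan;
  return arma::dot(ca, cb) / std::sqrt(na2 * nb2);
}

static double group_cor(const arma::vec& a, const arma::vec& b, bool spearman) {
  if (spearman) return pearson_or_nan(avg_ranks(a), avg_ranks(b));
  return pearson_or_nan(a, b);
}

// [[Rcpp::export]]
List cpp_ltm_screen(const arma::mat& m, const arma::uvec& clock_idx,
                    const arma::mat& ref, const arma::uvec& driver_idx,
                    const arma::ivec& ks, const bool clock_spearman,
                    const bool flavor_spearman) {
  const arma::uword G = m.n_rows, n = m.n_cols;
  const arma::uword nc = clock_idx.n_elem;
  const arma::uword nd = driver_idx.n_elem, nk = ks.n_elem;

  arma::mat m2 = arma::square(m);  // for per-group sums of squares
  arma::mat R_ncv(nd, nk), R_zstat(nd, nk);
  R_ncv.fill(arma::datum::nan);
  R_zstat.fill(arma::datum::nan);

  // lower-triangle reference entries, row-major over i > j
  arma::vec acc(G), acc2(G);

  for (arma::uword d = 0; d < nd; ++d) {
    arma::rowvec x = m.row(driver_idx(d));
    arma::uvec ord = arma::stable_sort_index(x.t());

    for (arma::uword kk = 0; kk < nk; ++kk) {
      const arma::uword k = (arma::uword)ks(kk);
      arma::vec mean_driver(k), mean_ncv(k), zstat(k);

      arma::uword start = 0;
      for (arma::uword g = 0; g < k; ++g) {
        // boundary at ceiling((g+1) * n / k)
        arma::uword end = ((g + 1) * n + k - 1) / k;
        const arma::uword ng = end - start;

        acc.zeros();
        acc2.zeros();
        double dsum = 0.0;
        for (arma::uword t = start; t < end; ++t) {
          const arma::uword c = ord(t);
          acc += m.col(c);
          acc2 += m2.col(c);
          dsum += x(c);
        }
        mean_driver(g) = dsum / (double)ng;

        // per-gene CV; denominator = mean CV over genes with positive mean
        double cv_sum = 0.0;
        arma::uword cv_n = 0;
        arma::vec cv(G, arma::fill::value(arma::datum::nan));
        for (arma::uword r = 0; r < G; ++r) {
          const double mu = acc(r) / (double)ng;
          if (mu > 0.0) {
            double var = (acc2(r) - (double)ng * mu * mu) / ((double)ng - 1.0);
            if (var < 0.0) var = 0.0;
            cv(r) = std::sqrt(var) / mu;
            cv_sum += cv(r);
            ++cv_n;
          }
        }
        const double denom = (cv_n > 0) ? cv_sum / (double)cv_n : 0.0;

        double ncv_sum = 0.0;
        for (arma::uword ci = 0; ci < nc; ++ci) {
          const double cvg = cv(clock_idx(ci));
          if (std::isfinite(cvg) && cvg > 0.0 && denom > 0.0) {
            ncv_sum += cvg / denom;
          }  // constant or zero-mean clock gene contributes nCV 0
        }
        mean_ncv(g) = ncv_sum / (double)nc;

        // clock-gene correlation matrix of this group vs reference
        arma::mat sub(nc, ng);
        for (arma::uword t = 0; t < ng; ++t) {
          const arma::uword c = ord(start + t);
          for (arma::uword ci = 0; ci < nc; ++ci) {
            sub(ci, t) = m(clock_idx(ci), c);
          }
        }
        if (clock_spearman) {
          for (arma::uword ci = 0; ci < nc; ++ci) {
            sub.row(ci) = avg_ranks(sub.row(ci).t()).t();
          }
        }
        arma::vec rmu = arma::mean(sub, 1);
        sub.each_col() -= rmu;
        arma::vec norms(nc);
        for (arma::uword ci = 0; ci < nc; ++ci) {
          norms(ci) = std::sqrt(arma::dot(sub.row(ci), sub.row(ci)));
        }
        double z = 0.0;
        for (arma::uword i = 1; i < nc; ++i) {
          for (arma::uword j = 0; j < i; ++j) {
            double q = 0.0;
            if (norms(i) > 0.0 && norms(j) > 0.0) {
              q = arma::dot(sub.row(i), sub.row(j)) / (norms(i) * norms(j));
            }
            z += q * ref(i, j);
          }
        }
        zstat(g) = z;

        start = end;
      }

      R_ncv(d, kk) = group_cor(mean_driver, mean_ncv, flavor_spearman);
      R_zstat(d, kk) = group_cor(mean_driver, zstat, flavor_spearman);
    }
    if (d % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["r_ncv"] = R_ncv, _["r_zstat"] = R_zstat);
}
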