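#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cross-recurrence diagonal-line scan without materialising the binary
// matrix in R. Distances are computed once into a flat buffer (used both for
// the fixed-recurrence-rate epsilon quantile and for the diagonal run-length
// histogram). Large problems (> 2^21 pairs) use single-precision distances
// and a strided quantile sample; small problems stay in double precision and
// match the R matrix path exactly.

template <typename Real>
static List cra_scan_impl(const NumericMatrix& A, const NumericMatrix& B,
                          double eps, double rr_target, bool fixed_eps,
                          int lmin) {
  const int na = A.nrow(), nb = B.nrow(), m = A.ncol();
  const R_xlen_t ntot = (R_xlen_t)na * nb;
  const double* pa = REAL(A);
  const double* pb = REAL(B);

  std::vector<Real> d2(ntot);
  {
    Real* out = d2.data();
    for (int j = 0; j < nb; ++j) {
      for (int i = 0; i < na; ++i) {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = pa[i + (R_xlen_t)k * na] - pb[j + (R_xlen_t)k * nb];
          s += d * d;
        }
        *out++ = (Real)s;
      }
    }
  }

  Real eps2;
  if (fixed_eps) {
    eps2 = (Real)(eps * eps);
  } else {
    // epsilon = rr_target quantile of the pairwise squared distances; above
    // ~10^6 pairs a deterministic stride sample of ~5*10^5 values is used
    // (quantile standard error < 0.05% recurrence rate)
    const R_xlen_t cap = 500000;
    R_xlen_t stride = ntot > 2 * cap ? ntot / cap : 1;
    std::vector<Real> cp;
    cp.reserve(ntot / stride + 1);
    for (R_xlen_t t = 0; t < ntot; t += stride) cp.push_back(d2[t]);
    R_xlen_t m_ = (R_xlen_t)cp.size();
    R_xlen_t k = (R_xlen_t)std::floor(rr_target * (double)(m_ - 1));
    if (k < 0) k = 0;
    if (k > m_ - 1) k = m_ - 1;
    std::nth_element(cp.begin(), cp.begin() + k, cp.end());
    eps2 = cp[k];
  }

  // recurrence indicator packed into bytes (cache-friendly diagonal walks)
  std::vector<unsigned char> rec8(ntot);
  R_xlen_t nrec = 0;
  for (R_xlen_t t = 0; t < ntot; ++t) {
    rec8[t] = d2[t] <= eps2;
    nrec += rec8[t];
  }

  // diagonal run-length histogram over all diagonals
  std::vector<R_xlen_t> hist;  // hist[l-1] = lines of length l
  long mdl = 0;
  for (int d = -(nb - 1); d <= na - 1; ++d) {
    int i = d >= 0 ? d : 0;
    int j = d >= 0 ? 0 : -d;
    long run = 0;
    while (i < na && j < nb) {
      if (rec8[(R_xlen_t)j * na + i]) {
        ++run;
      } else if (run > 0) {
        if ((size_t)run > hist.size()) hist.resize(run, 0);
        hist[run - 1]++;
        if (run > mdl) mdl = run;
        run = 0;
      }
      ++i; ++j;
    }
    if (run > 0) {
      if ((size_t)run > hist.size()) hist.resize(run, 0);
      hist[run - 1]++;
      if (run > mdl) mdl = run;
    }
  }

  double pts_all = 0, pts_lmin = 0, nlines_lmin = 0;
  for (size_t l = 1; l <= hist.size(); ++l) {
    pts_all += (double)l * hist[l - 1];
    if ((int)l >= lmin) {
      pts_lmin += (double)l * hist[l - 1];
      nlines_lmin += hist[l - 1];
    }
  }
  double det = pts_all > 0 ? pts_lmin / pts_all : 0.0;
  double L = nlines_lmin > 0 ? pts_lmin / nlines_lmin : 0.0;
  double entr = 0.0;
  if (nlines_lmin > 0) {
    for (size_t l = lmin; l <= hist.size(); ++l) {
      if (hist[l - 1] > 0) {
        double p = hist[l - 1] / nlines_lmin;
        entr -= p * std::log(p);
      }
    }
  }

  IntegerVector hist_out(hist.size());
  for (size_t l = 0; l < hist.size(); ++l) hist_out[l] = (int)hist[l];
  return List::create(
    _["RR"] = (double)nrec / (double)ntot,
    _["DET"] = det,
    _["L"] = L,
    _["MDL"] = (double)mdl,
    _["ENTR"] = entr,
    _["eps"] = std::sqrt((double)eps2),
    _["lmin"] = lmin,
    _["line_histogram"] = hist_out);
}

// [[Rcpp::export(name = ".cra_scan_cpp")]]
List cra_scan_cpp(NumericMatrix A, NumericMatrix B,
                  double eps, double rr_target, bool fixed_eps, int lmin) {
  if (B.ncol() != A.ncol()) stop("trajectory dimension mismatch");
  const R_xlen_t ntot = (R_xlen_t)A.nrow() * B.nrow();
  if (ntot <= (R_xlen_t)1 << 21) {
    return cra_scan_impl<double>(A, B, eps, rr_target, fixed_eps, lmin);
  }
  return cra_scan_impl<float>(A, B, eps, rr_target, fixed_eps, lmin);
}

// False-nearest-neighbour fractions for embedding dimensions 1..m_max
// (Kennel criterion with exhaustive neighbour search).
// [[Rcpp::export(name = ".fnn_fractions_cpp")]]
NumericVector fnn_fractions_cpp(NumericVector x, int tau, int m_max,
                                double rtol, double atol, int theiler) {
  const int n = x.size();
  double mu = 0, s2 = 0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; ++i) s2 += (x[i] - mu) * (x[i] - mu);
  double sigma = std::sqrt(s2 / (n - 1));

  NumericVector out(m_max, NA_REAL);
  for (int m = 1; m <= m_max; ++m) {
    int npts = n - m * tau;  // one more coordinate needed for the m+1 test
    if (npts < 10) break;
    long nfalse = 0, ntested = 0;
    for (int i = 0; i < npts; ++i) {
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < npts; ++j) {
        if (std::abs(j - i) <= theiler) continue;  // exclude temporal neighbours
        double d = 0;
        for (int k = 0; k < m; ++k) {
          double dd = x[i + k * tau] - x[j + k * tau];
          d += dd * dd;
          if (d >= best) break;
        }
        if (d < best) { best = d; jbest = j; }
      }
      if (jbest < 0) continue;
      double rm = std::sqrt(best);
      double extra = std::fabs(x[i + m * tau] - x[jbest + m * tau]);
      double rm1 = std::sqrt(best + extra * extra);
      ++ntested;
      bool false_nb = false;
      // numerically coincident neighbours (exact repeats of a periodic
      // signal) are true neighbours; the distance-growth ratio is noise there
      const double floor_ = 1e-10 * sigma;
      if (rm > floor_ && extra / rm > rtol) false_nb = true;
      if (rm1 / sigma > atol) false_nb = true;
      if (rm <= floor_ && extra > floor_) false_nb = true;
      if (false_nb) ++nfalse;
    }
    out[m - 1] = ntested > 0 ? (double)nfalse / ntested : NA_REAL;
  }
  return out;
}
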