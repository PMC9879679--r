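#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Higuchi curve-length fractal dimension.
// For each scale k = 1..kmax and offset m, the normalized curve length is
//   L_m(k) = (sum |x[m+ik] - x[m+(i-1)k]|) * (N-1) / (floor((N-m)/k) * k) / k
// and the estimate is the slope of log(mean_m L_m(k)) against log(1/k).
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  const int n = x.size();
  std::vector<double> logl, logk;
  double xmin = x[0], xmax = x[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]);
    xmax = std::max(xmax, x[i]);
  }
  if (xmax - xmin <= 0.0) return 1.0;  // constant series: degenerate branch
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    int nm = 0;
    for (int m = 0; m < k; ++m) {
      const int np = (n - 1 - m) / k;  // number of increments at this offset
      if (np < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= np; ++i)
        s += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      lsum += s * double(n - 1) / (double(np) * k) / k;
      ++nm;
    }
    if (nm == 0 || lsum <= 0.0) continue;
    logl.push_back(std::log(lsum / nm));
    logk.push_back(std::log(1.0 / k));
  }
  const int p = logl.size();
  if (p < 2) return 1.0;
  double mx = 0, my = 0;
  for (int i = 0; i < p; ++i) { mx += logk[i]; my += logl[i]; }
  mx /= p; my /= p;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < p; ++i) {
    sxy += (logk[i] - mx) * (logl[i] - my);
    sxx += (logk[i] - mx) * (logk[i] - mx);
  }
  return sxy / sxx;
}

// Approximate entropy, Chebyshev distance, self-matches included:
// ApEn = phi^m(r) - phi^{m+1}(r) with
// phi^m = (N-m+1)^{-1} sum_i log C_i^m,  C_i^m = #{j : d(U_i,U_j) <= r}/(N-m+1).
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (r <= 0.0) return 0.0;
  const int nv1 = n - m + 1;      // template count at length m
  const int nv2 = n - m;          // template count at length m+1
  if (nv2 < 1) return 0.0;
  const double* px = REAL(x);
  // self-matches: every template matches itself
  std::vector<int> c1(nv1, 1), c2(nv2, 1);
  // one symmetric pass: extend the length-m Chebyshev check by one sample
  for (int i = 0; i < nv1; ++i) {
    for (int j = i + 1; j < nv1; ++j) {
      double dmax = 0.0;
      int t = 0;
      for (; t < m; ++t) {
        const double d = std::fabs(px[i + t] - px[j + t]);
        if (d > dmax) dmax = d;
        if (dmax > r) break;
      }
      if (t < m) continue;        // early exit: no match at length m
      ++c1[i]; ++c1[j];
      if (i < nv2 && j < nv2) {
        const double d = std::fabs(px[i + m] - px[j + m]);
        if (d <= r && dmax <= r) { ++c2[i]; ++c2[j]; }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nv1; ++i) phi1 += std::log(double(c1[i]) / nv1);
  for (int i = 0; i < nv2; ++i) phi2 += std::log(double(c2[i]) / nv2);
  return phi1 / nv1 - phi2 / nv2;
}

// Grassberger-Procaccia correlation dimension: delay-embed, count pairs
// closer than epsilon over a log-spaced grid spanning the 5th-50th
// percentile of pairwise Euclidean distances, return the least-squares
// slope of log C(eps) against log eps.
// [[Rcpp::export(name = ".corrdim_cpp")]]
double corrdim_cpp(NumericVector x, int embed_m, int delay, int n_eps) {
  const int n = x.size();
  const int nv = n - (embed_m - 1) * delay;
  if (nv < 2) return 0.0;
  std::vector<double> d;
  d.reserve(size_t(nv) * (nv - 1) / 2);
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      // extended-precision accumulation (as R's sum()) so that threshold
      // counts match a vectorized R implementation bit for bit
      long double s = 0.0L;
      for (int t = 0; t < embed_m; ++t) {
        const double df = x[i + t * delay] - x[j + t * delay];
        const double sq = df * df;   // square in double, accumulate extended
        s += sq;
      }
      d.push_back(std::sqrt((double)s));
    }
  }
  const size_t np = d.size();
  std::vector<double> work(d);
  std::nth_element(work.begin(), work.begin() + size_t(0.05 * (np - 1)),
                   work.end());
  const double lo = work[size_t(0.05 * (np - 1))];
  std::nth_element(work.begin(), work.begin() + size_t(0.50 * (np - 1)),
                   work.end());
  const double hi = work[size_t(0.50 * (np - 1))];
  if (!(hi > lo) || lo <= 0.0) return 0.0;  // identical / degenerate points
  // pairs strictly closer than each log-spaced epsilon
  const double llo = std::log(lo), lhi = std::log(hi);
  std::vector<double> le, lc;
  for (int g = 0; g < n_eps; ++g) {
    const double eps = std::exp(llo + (lhi - llo) * g / (n_eps - 1));
    size_t cnt = 0;
    for (size_t t = 0; t < np; ++t) cnt += (d[t] < eps);
    if (cnt == 0) continue;
    le.push_back(std::log(eps));
    lc.push_back(std::log(double(cnt) / np));
  }
  const int p = le.size();
  if (p < 2) return 0.0;
  double mx = 0, my = 0;
  for (int i = 0; i < p; ++i) { mx += le[i]; my += lc[i]; }
  mx /= p; my /= p;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < p; ++i) {
    sxy += (le[i] - mx) * (lc[i] - my);
    sxx += (le[i] - mx) * (le[i] - mx);
  }
  if (sxx <= 0.0) return 0.0;
  const double slope = sxy / sxx;
  return slope > 0.0 ? slope : 0.0;
}
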