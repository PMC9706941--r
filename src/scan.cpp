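// Two-group log-rank scan kernel: for each candidate threshold c the
// cohort splits into {interval <= c} vs {interval > c} and the arms'
// post-failure survival is compared by the log-rank statistic with
// hypergeometric variance at ties.  Hot path of the cut-point scan and
// its resampling correction, so the inner loops run on plain arrays.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".scan_logrank")]]
List scan_logrank(NumericVector post_time, IntegerVector death,
                  NumericVector intervals, NumericVector grid,
                  int min_events) {
  const int n = post_time.size(), C = grid.size();

  // copy into time-sorted plain arrays once
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double *ptp = REAL(post_time);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return ptp[a] < ptp[b]; });
  std::vector<double> pt(n), iv(n);
  std::vector<char> dd(n);
  int total_deaths = 0;
  for (int i = 0; i < n; ++i) {
    const int k = ord[i];
    pt[i] = post_time[k];
    iv[i] = intervals[k];
    dd[i] = (char)death[k];
    total_deaths += death[k];
  }

  NumericVector p(C), chi(C);
  IntegerVector early_n(C), late_n(C), early_d(C), late_d(C);

  for (int c = 0; c < C; ++c) {
    const double thr = grid[c];
    int n1 = 0, d1_tot = 0;
    for (int i = 0; i < n; ++i) {
      if (iv[i] <= thr) {
        ++n1;
        if (dd[i]) ++d1_tot;
      }
    }
    early_n[c] = n1;
    late_n[c] = n - n1;
    early_d[c] = d1_tot;
    late_d[c] = total_deaths - d1_tot;

    const bool inadmissible = d1_tot < min_events ||
                              (total_deaths - d1_tot) < min_events;
    if (inadmissible) {
      p[c] = NA_REAL;
      chi[c] = NA_REAL;
      continue;
    }

    double OE = 0.0, V = 0.0;
    int risk1 = n1;
    int i = 0;
    while (i < n) {
      int j = i, d = 0, d1 = 0;
      const double t = pt[i];
      while (j < n && pt[j] == t) {
        if (dd[j]) {
          ++d;
          if (iv[j] <= thr) ++d1;
        }
        ++j;
      }
      if (d > 0) {
        const int nrisk = n - i;
        const double p1 = (double)risk1 / nrisk;
        OE += d1 - d * p1;
        if (nrisk > 1)
          V += (double)d * (nrisk - d) / (nrisk - 1) * p1 * (1.0 - p1);
      }
      for (int k = i; k < j; ++k)
        if (iv[k] <= thr) --risk1;
      i = j;
    }
    if (V <= 0.0) {
      p[c] = NA_REAL;
      chi[c] = NA_REAL;
    } else {
      chi[c] = OE * OE / V;
      p[c] = R::pchisq(chi[c], 1.0, 0, 0);
    }
  }
  return List::create(_["p"] = p, _["chi"] = chi,
                      _["early_n"] = early_n, _["late_n"] = late_n,
                      _["early_deaths"] = early_d, _["late_deaths"] = late_d);
}

// Null distribution of the minimum scan P under interval permutation:
// permutes `intervals` in place B times (R's RNG, so seeded from R) and
// returns each permutation's minimum admissible P (1 when none).
// [[Rcpp::export(name = ".scan_perm_min_p")]]
NumericVector scan_perm_min_p(NumericVector post_time, IntegerVector death,
                              NumericVector intervals, NumericVector grid,
                              int min_events, int n_resamples) {
  const int n = intervals.size();
  NumericVector out(n_resamples);
  NumericVector iv = clone(intervals);
  for (int b = 0; b < n_resamples; ++b) {
    // Fisher-Yates with R's RNG (matches sample.int's unbiasedness;
    // stream differs from R's sample(), which only affects which
    // permutations are drawn, not their law)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(iv[i], iv[j]);
    }
    List ks = scan_logrank(post_time, death, iv, grid, min_events);
    NumericVector pv = ks["p"];
    double m = 2.0;
    for (int c = 0; c < pv.size(); ++c)
      if (!NumericVector::is_na(pv[c]) && pv[c] < m) m = pv[c];
    out[b] = (m > 1.0) ? 1.0 : m;
  }
  return out;
}
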