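// 1-D K-means engine: Lloyd's algorithm on sorted data with
// squared-distance-weighted ("k-means++"-style) seeding.
//
// The randomness contract is part of the measure's reproducibility
// guarantee and is mirrored by the pure-R reference implementation used in
// the test suite: one restart consumes exactly k uniform deviates from R's
// RNG (the first centre is a uniform pick over points in their original
// order; each later centre is the smallest index whose cumulative squared
// distance to the nearest chosen centre reaches u * total), restarts run
// in order, and the restart with strictly smallest within-cluster sum of
// squares wins. Lloyd assignment uses the interval rule on sorted values:
// cluster j receives values in (m[j-1], m[j]] where m are midpoints of
// consecutive sorted centres. An empty cluster is reseeded once at the
// point farthest from its assigned centre, then dropped if it recurs.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static void seed_centers(const std::vector<double>& v, int k,
                         std::vector<double>& cen,
                         std::vector<double>& d2,
                         std::vector<double>& cw) {
  const int n = (int)v.size();
  int idx = (int)std::floor(unif_rand() * n);
  if (idx > n - 1) idx = n - 1;
  cen[0] = v[idx];
  if (k == 1) return;
  {
    // cumulative weights accumulated in long double, stored as double,
    // matching R's cumsum()
    long double acc = 0.0L;
    for (int i = 0; i < n; ++i) {
      const double d = v[i] - cen[0];
      d2[i] = d * d;
      acc += d2[i];
      cw[i] = (double)acc;
    }
  }
  for (int j = 1; j < k; ++j) {
    const double u = unif_rand() * cw[n - 1];
    int pick = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
    if (pick > n - 1) pick = n - 1;
    cen[j] = v[pick];
    if (j == k - 1) break; // d2 no longer consulted after the last pick
    long double acc = 0.0L;
    for (int i = 0; i < n; ++i) {
      const double d = v[i] - cen[j];
      const double nd = d * d;
      if (nd < d2[i]) d2[i] = nd;
      acc += d2[i];
      cw[i] = (double)acc;
    }
  }
}

// boundary positions pos[j] = #{ sv <= midpoint(cen[j], cen[j+1]) }
static void boundaries(const std::vector<double>& sv,
                       const std::vector<double>& cen,
                       std::vector<int>& pos) {
  const int k = (int)cen.size();
  pos.assign(k - 1, 0);
  for (int j = 0; j + 1 < k; ++j) {
    const double m = (cen[j] + cen[j + 1]) / 2.0;
    pos[j] = (int)(std::upper_bound(sv.begin(), sv.end(), m) - sv.begin());
  }
}

static void lloyd_sorted(const std::vector<double>& sv,
                         const std::vector<double>& cs1,
                         std::vector<double>& cen,
                         int max_iter, double tol,
                         std::vector<int>& cnt_out) {
  const int n = (int)sv.size();
  bool reseeded = false;
  int iter = 0;
  std::vector<int> pos, cnt;
  while (true) {
    ++iter;
    const int k = (int)cen.size();
    if (k == 1) break;
    boundaries(sv, cen, pos);
    cnt.assign(k, 0);
    bool any_empty = false;
    {
      int lo = 0;
      for (int j = 0; j < k; ++j) {
        const int hi = (j == k - 1) ? n : pos[j];
        cnt[j] = hi - lo;
        if (cnt[j] == 0) any_empty = true;
        lo = hi;
      }
    }
    if (any_empty) {
      if (!reseeded) {
        reseeded = true;
        double best = -1.0;
        int far = 0, lo = 0;
        for (int j = 0; j < k; ++j) {
          const int hi = (j == k - 1) ? n : pos[j];
          for (int i = lo; i < hi; ++i) {
            const double d = std::fabs(sv[i] - cen[j]);
            if (d > best) { best = d; far = i; }
          }
          lo = hi;
        }
        for (int j = 0; j < k; ++j) {
          if (cnt[j] == 0) { cen[j] = sv[far]; break; }
        }
        std::sort(cen.begin(), cen.end());
      } else {
        std::vector<double> keep;
        for (int j = 0; j < k; ++j) if (cnt[j] > 0) keep.push_back(cen[j]);
        cen.swap(keep);
      }
      if (iter >= max_iter) break;
      continue;
    }
    double delta = 0.0;
    {
      int lo = 0;
      for (int j = 0; j < k; ++j) {
        const int hi = (j == k - 1) ? n : pos[j];
        const double mean = (cs1[hi] - cs1[lo]) / (double)(hi - lo);
        const double mv = std::fabs(mean - cen[j]);
        if (mv > delta) delta = mv;
        cen[j] = mean;
        lo = hi;
      }
    }
    if (delta < tol || iter >= max_iter) break;
  }
  // final pass: merge coincident centres, drop empties, fix counts
  while (true) {
    cen.erase(std::unique(cen.begin(), cen.end()), cen.end());
    const int k = (int)cen.size();
    if (k == 1) {
      cnt_out.assign(1, n);
      cen[0] = cs1[n] / (double)n;
      return;
    }
    boundaries(sv, cen, pos);
    cnt_out.assign(k, 0);
    bool any_empty = false;
    int lo = 0;
    for (int j = 0; j < k; ++j) {
      const int hi = (j == k - 1) ? n : pos[j];
      cnt_out[j] = hi - lo;
      if (cnt_out[j] == 0) any_empty = true;
      lo = hi;
    }
    if (!any_empty) return;
    std::vector<double> keep;
    for (int j = 0; j < k; ++j) if (cnt_out[j] > 0) keep.push_back(cen[j]);
    cen.swap(keep);
  }
}

// [[Rcpp::export]]
List cpp_kmeans1d(NumericVector values, int k, int n_restarts, int max_iter,
                  double tol) {
  const int n = values.size();
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> sv(v);
  std::sort(sv.begin(), sv.end());
  std::vector<double> cs1(n + 1, 0.0), cs2(n + 1, 0.0);
  long double a1 = 0.0L, a2 = 0.0L;
  for (int i = 0; i < n; ++i) {
    a1 += sv[i];
    a2 += (long double)sv[i] * sv[i];
    cs1[i + 1] = (double)a1;
    cs2[i + 1] = (double)a2;
  }
  std::vector<double> d2(n), cw(n);
  std::vector<double> best_cen;
  std::vector<int> best_cnt;
  double best_w = 0.0;
  bool have = false;
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<double> cen(k);
    seed_centers(v, k, cen, d2, cw);
    std::sort(cen.begin(), cen.end());
    std::vector<int> cnt;
    lloyd_sorted(sv, cs1, cen, max_iter, tol, cnt);
    double w = 0.0;
    int lo = 0;
    for (size_t j = 0; j < cen.size(); ++j) {
      const int hi = lo + cnt[j];
      w += (cs2[hi] - cs2[lo]) - (double)cnt[j] * cen[j] * cen[j];
      lo = hi;
    }
    if (!have || w < best_w) {
      have = true;
      best_w = w;
      best_cen = cen;
      best_cnt = cnt;
    }
  }
  return List::create(_["centers"] = NumericVector(best_cen.begin(), best_cen.end()),
                      _["counts"] = IntegerVector(best_cnt.begin(), best_cnt.end()),
                      _["wcss"] = best_w);
}
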