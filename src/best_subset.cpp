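// Exhaustive best-subset search over precomputed Gram matrices.
//
// For every support of size 0..max_support drawn from m candidate
// columns, solves the least-squares normal equations (with intercept)
// from the Gram matrix G = [1 X]'[1 X] and Gy = [1 X]'y, and records
// the minimal residual sum of squares per support size.  The
// enumeration nests the combination loops so the Cholesky factor of
// the bordered normal matrix is extended incrementally one column at a
// time (the innermost loop only computes one new factor row).
// Supports whose normal equations are numerically singular are
// skipped.  Exact ties (within 1e-12 relative RSS) are all returned so
// the caller can apply its deterministic tie-breaking.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>

using namespace Rcpp;

namespace {

struct BestTracker {
  double best_rss = R_PosInf;
  std::vector<std::vector<int>> ties;
  long skipped = 0;

  void offer(double rss, const std::vector<int> &idx, int depth) {
    if (!R_FINITE(best_rss)) {
      best_rss = rss;
      ties.assign(1, std::vector<int>(idx.begin() + 1, idx.begin() + depth));
      return;
    }
    double tol = 1e-12 * (1.0 + std::abs(best_rss));
    if (rss < best_rss - tol) {
      best_rss = rss;
      ties.assign(1, std::vector<int>(idx.begin() + 1, idx.begin() + depth));
    } else if (std::abs(rss - best_rss) <= tol && ties.size() < 64) {
      ties.emplace_back(idx.begin() + 1, idx.begin() + depth);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".best_subsets_cpp")]]
List best_subsets_cpp(NumericMatrix G, NumericVector Gy, double yty,
                      int max_support) {
  const int m = G.ncol() - 1;  // candidate columns (col 0 = intercept)
  const int K = max_support;
  std::vector<BestTracker> track(K + 1);

  // flat column-major copy of G for pointer access in the hot loop
  const int dim = m + 1;
  std::vector<double> Gf(G.begin(), G.end());
  const double *gp = Gf.data();

  // L: lower-triangular Cholesky factor rows for the current nested
  // support [intercept, c1, .., cd]; z: forward-solved rhs; both are
  // extended one row per recursion level.
  const int D = K + 1;
  std::vector<double> L(D * D, 0.0);
  std::vector<double> z(D, 0.0);
  std::vector<int> idx(D, 0);

  // level 0: intercept only
  double l00 = std::sqrt(G(0, 0));
  L[0] = l00;
  z[0] = Gy[0] / l00;
  idx[0] = 0;
  {
    double rss = yty - z[0] * z[0];
    track[0].offer(rss < 0 ? 0 : rss, idx, 1);
  }

  // iterative nesting: depth d in 1..K, candidate j > idx[d-1] (for
  // d >= 2) to enumerate combinations in increasing order
  std::function<void(int)> descend = [&](int depth) {
    const int lo = (depth == 1) ? 1 : idx[depth - 1] + 1;
    for (int j = lo; j <= m; ++j) {
      // extend the Cholesky factor with column j
      const double *gj = gp + (size_t)j * dim;
      double *Lrow = &L[depth * D];
      double diag = gj[j];
      for (int k = 0; k < depth; ++k) {
        double v = gj[idx[k]];
        const double *Lk = &L[k * D];
        for (int t = 0; t < k; ++t) v -= Lrow[t] * Lk[t];
        v /= Lk[k];
        Lrow[k] = v;
        diag -= v * v;
      }
      if (diag <= 1e-10 * std::abs(gj[j]) || diag <= 0.0) {
        ++track[depth].skipped;
        continue;
      }
      Lrow[depth] = std::sqrt(diag);
      double zj = Gy[j];
      for (int t = 0; t < depth; ++t) zj -= Lrow[t] * z[t];
      zj /= Lrow[depth];
      z[depth] = zj;
      idx[depth] = j;

      // RSS = y'y - ||z||^2 for the current support
      double q = 0.0;
      for (int t = 0; t <= depth; ++t) q += z[t] * z[t];
      double rss = yty - q;
      if (rss < 0) rss = 0;
      track[depth].offer(rss, idx, depth + 1);

      if (depth < K) descend(depth + 1);
    }
  };
  if (K >= 1 && m >= 1) descend(1);

  List per_size(K + 1);
  for (int s = 0; s <= K; ++s) {
    List tl(track[s].ties.size());
    for (size_t t = 0; t < track[s].ties.size(); ++t) {
      tl[t] = IntegerVector(track[s].ties[t].begin(),
                            track[s].ties[t].end());
    }
    per_size[s] = List::create(_["rss"] = track[s].best_rss,
                               _["supports"] = tl,
                               _["skipped"] = (double)track[s].skipped);
  }
  return per_size;
}
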