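#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sample-aware refinement of MAPN cluster centers. Every modal-K chain sample
// holds exactly K emitter positions, one per physical emitter, so cluster
// membership is refined under the constraint that each sample contributes
// exactly one member per cluster: per sample, emitters are matched one-to-one
// to the current centers greedily by distance, then centers are recomputed
// from their matched members. Plain pooled k-means can split one wide
// posterior cluster and merge two tight ones; this constrained pass cannot.
//
// mu, a: stacked emitter draws (rows), nloc their allocation counts;
// start/len: row ranges of the modal-K samples; centers0: initial centers.
// [[Rcpp::export]]
List mapn_refine_cpp(NumericMatrix mu, NumericMatrix a, NumericVector nloc,
                     IntegerVector start, IntegerVector len,
                     NumericMatrix centers0, int iters) {
  int K = centers0.nrow();
  int S = start.size();
  std::vector<double> cx(K), cy(K);
  for (int k = 0; k < K; ++k) { cx[k] = centers0(k, 0); cy[k] = centers0(k, 1); }
  std::vector<double> sx(K), sy(K), sxx(K), syy(K), sax(K), say(K), snl(K);
  std::vector<int> cnt(K);
  std::vector<int> match(K);
  typedef std::pair<double, int> P;
  std::vector<P> pairs; pairs.reserve((size_t)K * K);
  for (int it = 0; it < iters; ++it) {
    std::fill(sx.begin(), sx.end(), 0.0); std::fill(sy.begin(), sy.end(), 0.0);
    std::fill(sxx.begin(), sxx.end(), 0.0); std::fill(syy.begin(), syy.end(), 0.0);
    std::fill(sax.begin(), sax.end(), 0.0); std::fill(say.begin(), say.end(), 0.0);
    std::fill(snl.begin(), snl.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int s = 0; s < S; ++s) {
      int r0 = start[s];
      if (len[s] != K) continue;
      pairs.clear();
      for (int e = 0; e < K; ++e) {
        double ex = mu(r0 + e, 0), ey = mu(r0 + e, 1);
        for (int c = 0; c < K; ++c) {
          double dx = ex - cx[c], dy = ey - cy[c];
          pairs.push_back(P(dx * dx + dy * dy, e * K + c));
        }
      }
      std::sort(pairs.begin(), pairs.end());
      std::vector<char> eu(K, 0), cu(K, 0);
      int used = 0;
      for (size_t q = 0; q < pairs.size() && used < K; ++q) {
        int e = pairs[q].second / K, c = pairs[q].second % K;
        if (eu[e] || cu[c]) continue;
        eu[e] = 1; cu[c] = 1; ++used;
        match[e] = c;
      }
      for (int e = 0; e < K; ++e) {
        int c = match[e], r = r0 + e;
        sx[c] += mu(r, 0); sy[c] += mu(r, 1);
        sxx[c] += mu(r, 0) * mu(r, 0); syy[c] += mu(r, 1) * mu(r, 1);
        sax[c] += a(r, 0); say[c] += a(r, 1);
        snl[c] += nloc[r]; cnt[c] += 1;
      }
    }
    for (int k = 0; k < K; ++k) if (cnt[k] > 0) {
      cx[k] = sx[k] / cnt[k]; cy[k] = sy[k] / cnt[k];
    }
  }
  NumericMatrix centers(K, 2), sd(K, 2), am(K, 2);
  NumericVector nl(K); IntegerVector n(K);
  for (int k = 0; k < K; ++k) {
    centers(k, 0) = cx[k]; centers(k, 1) = cy[k];
    if (cnt[k] > 1) {
      sd(k, 0) = std::sqrt(std::max(0.0, (sxx[k] - sx[k] * sx[k] / cnt[k]) / (cnt[k] - 1)));
      sd(k, 1) = std::sqrt(std::max(0.0, (syy[k] - sy[k] * sy[k] / cnt[k]) / (cnt[k] - 1)));
    } else { sd(k, 0) = NA_REAL; sd(k, 1) = NA_REAL; }
    if (cnt[k] > 0) {
      am(k, 0) = sax[k] / cnt[k]; am(k, 1) = say[k] / cnt[k];
      nl[k] = snl[k] / cnt[k];
    } else { am(k, 0) = am(k, 1) = 0.0; nl[k] = NA_REAL; }
    n[k] = cnt[k];
  }
  return List::create(_["centers"] = centers, _["sd"] = sd, _["a"] = am,
                      _["n_loc"] = nl, _["n_members"] = n);
}
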