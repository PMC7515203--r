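#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// One-vs-rest Wilcoxon rank-sum sufficient statistics per gene over a
// column-sparse cell x gene matrix of (already log-normalized) values.
// Zeros share one big tie group, so only the nonzero entries of each gene
// need sorting. Returns, per gene and cluster: the rank sum W of the
// cluster's cells, the global tie correction term sum(t^3 - t), and the
// per-cluster mean value (zeros included).
// [[Rcpp::export]]
List ranksum_stats(const IntegerVector& mat_i, const IntegerVector& mat_p,
                   const NumericVector& mat_x, int n_cells, int n_genes,
                   const IntegerVector& cluster, int K) {
  NumericMatrix W(K, n_genes), msum(K, n_genes);
  NumericVector tie(n_genes);
  std::vector<int> csize(K, 0);
  for (int i = 0; i < n_cells; ++i) csize[cluster[i]]++;

  std::vector<std::pair<double, int>> v;
  for (int g = 0; g < n_genes; ++g) {
    const int lo = mat_p[g], hi = mat_p[g + 1], nnz = hi - lo;
    const int nz = n_cells - nnz;  // zero count
    v.clear();
    v.reserve(nnz);
    std::vector<int> nzc(K, 0);
    for (int s = lo; s < hi; ++s) {
      v.emplace_back(mat_x[s], cluster[mat_i[s]]);
      nzc[v.back().second]++;
      msum(v.back().second, g) += mat_x[s];
    }
    std::sort(v.begin(), v.end());
    double tt = (double)nz * nz * nz - nz;  // zero tie block
    const double zrank = (nz + 1) / 2.0;    // average rank of the zeros
    for (int k = 0; k < K; ++k) {
      W(k, g) = (csize[k] - nzc[k]) * zrank;
    }
    int s = 0;
    while (s < nnz) {
      int e = s;
      while (e < nnz && v[e].first == v[s].first) ++e;
      const int t = e - s;
      if (t > 1) tt += (double)t * t * t - t;
      const double r = nz + (s + e + 1) / 2.0;  // average rank of the group
      for (int q = s; q < e; ++q) W(v[q].second, g) += r;
      s = e;
    }
    tie[g] = tt;
  }
  return List::create(_["W"] = W, _["tie"] = tie, _["mean_sum"] = msum,
                      _["cluster_size"] = wrap(csize));
}
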