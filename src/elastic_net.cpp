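#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net over a decreasing lambda
// path with warm starts, using covariance updates (sufficient statistics
// X'X and X'y), which makes each coordinate update O(p). X must be
// standardized (columns mean 0, variance 1 with 1/n denominator) and y
// centered; the objective is
//   (1/2n) ||y - X b||^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2).
// [[Rcpp::export]]
NumericMatrix en_path_cd(const NumericMatrix& X, const NumericVector& y,
                         const NumericVector& lambdas, double alpha,
                         double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix beta(p, L);
  std::vector<double> b(p, 0.0), xty(p, 0.0), g(p, 0.0);
  std::vector<double> xtx((size_t)p * p, 0.0);

  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * y[i];
    xty[j] = s / n;
    for (int k = j; k < p; ++k) {
      const double* xk = &X(0, k);
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += xj[i] * xk[i];
      xtx[(size_t)j * p + k] = xtx[(size_t)k * p + j] = c / n;
    }
  }
  // g[j] tracks (1/n) x_j' X b
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha;
    const double denom = 1.0 + lam * (1.0 - alpha);
    for (int it = 0; it < max_iter; ++it) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        const double z = xty[j] - g[j] + xtx[(size_t)j * p + j] * b[j];
        const double bn = soft(z, l1) / denom;
        const double del = bn - b[j];
        if (del != 0.0) {
          const double* col = &xtx[(size_t)j * p];
          for (int k = 0; k < p; ++k) g[k] += col[k] * del;
          if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
          b[j] = bn;
        }
      }
      if (maxdel < tol) break;
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}
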