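#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate descent for the elastic net on a fixed, decreasing lambda
// sequence with warm starts:
//
//   (1/2n) ||y - Xw||^2 + lambda * ( alpha ||w||_1 + (1-alpha)/2 ||w||^2 )
//
// X is expected column-standardized and y centered; nothing here enforces
// that, the caller owns the scaling. Returns a p x L matrix of solutions.
// [[Rcpp::export]]
NumericMatrix enet_path_cpp(NumericMatrix X, NumericVector y,
                            NumericVector lambdas, double alpha,
                            double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix W(p, L);
  std::vector<double> w(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  std::vector<double> xss(p);  // mean squared column norm x_j'x_j / n
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xss[j] = s / n;
  }
  std::vector<int> active;
  active.reserve(p);
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double thr = lam * alpha;          // soft threshold
    const double rdg = lam * (1.0 - alpha);  // ridge shrinkage
    auto update = [&](int j) -> double {     // returns scaled |change|
      if (xss[j] <= 0.0) { w[j] = 0.0; return 0.0; }
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
      g = g / n + xss[j] * w[j];  // partial residual correlation
      double wj = 0.0;
      if (g > thr)       wj = (g - thr) / (xss[j] + rdg);
      else if (g < -thr) wj = (g + thr) / (xss[j] + rdg);
      const double d = wj - w[j];
      if (d == 0.0) return 0.0;
      for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
      w[j] = wj;
      return std::fabs(d) * std::sqrt(xss[j]);
    };
    int it = 0;
    while (it < maxit) {
      // full sweep: updates everything and discovers the active set
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        const double del = update(j);
        if (del > maxdel) maxdel = del;
      }
      ++it;
      if (maxdel < tol) break;
      active.clear();
      for (int j = 0; j < p; ++j) if (w[j] != 0.0) active.push_back(j);
      // iterate only the active set until it converges, then re-check all
      while (it < maxit) {
        double mdel = 0.0;
        for (int j : active) {
          const double del = update(j);
          if (del > mdel) mdel = del;
        }
        ++it;
        if (mdel < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) W(j, l) = w[j];
  }
  return W;
}
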