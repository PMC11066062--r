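#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cyclic coordinate descent for the lasso on a standardized design.
//
// X must be column-standardized so that sum(x_j^2)/n == 1 and y centered;
// the objective is (1/2n) ||y - X b||^2 + lambda ||b||_1, solved with
// soft-thresholding updates b_j <- S(x_j' r / n + b_j, lambda). Lambdas
// must be decreasing; solutions are warm-started along the path. After
// convergence on the active set, one full sweep checks the KKT conditions
// for excluded coordinates.
//
// Returns a p x length(lambda) coefficient matrix on the standardized
// scale.
// [[Rcpp::export]]
NumericMatrix lasso_path_cpp(const NumericMatrix& X, const NumericVector& y,
                             const NumericVector& lambda,
                             double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix out(p, L);
  std::vector<double> beta(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  std::vector<char> active(p, 0);

  auto update_coord = [&](int j, double lam) -> double {
    const double* xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho = rho / n + beta[j];
    double bn = 0.0;
    if (rho > lam) bn = rho - lam;
    else if (rho < -lam) bn = rho + lam;
    double d = bn - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bn;
    }
    return std::fabs(d);
  };

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int it = 0; it < max_iter; ++it) {
      // iterate the active set to convergence
      double maxd;
      do {
        maxd = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!active[j]) continue;
          double d = update_coord(j, lam);
          if (d > maxd) maxd = d;
        }
      } while (maxd >= tol);
      // full sweep: KKT check over all coordinates
      maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        double d = update_coord(j, lam);
        if (d > maxd) maxd = d;
        if (beta[j] != 0.0) active[j] = 1;
      }
      if (maxd < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}
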