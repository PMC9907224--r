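#include <Rcpp.h>
using namespace Rcpp;

// Weighted lasso coordinate descent on the rotated profiled system:
// minimizes 0.5 * sum_i w_i (ystar_i - Xstar_i beta)^2 + lambda * sum_j v_j |beta_j|
// cycling over the columns listed in `work` (0-based, fixed input order).
// `r_in` is the current residual ystar - Xstar %*% beta and `xtx[j]` the
// precomputed sum_i w_i Xstar(i,j)^2. Convergence: the largest
// |delta beta_j| * sqrt(xtx[j]) in a sweep drops below `tol`.
// [[Rcpp::export]]
List cd_inner(NumericMatrix Xstar, NumericVector w, NumericVector r_in,
              NumericVector beta_in, NumericVector xtx, NumericVector v,
              double lambda, IntegerVector work, double tol, int maxit) {
  const int n = Xstar.nrow();
  NumericVector r = clone(r_in);
  NumericVector beta = clone(beta_in);
  int sweeps = 0;
  const int nw = work.size();
  for (int it = 0; it < maxit; ++it) {
    double maxd = 0.0;
    ++sweeps;
    for (int a = 0; a < nw; ++a) {
      const int j = work[a];
      const double* xj = &Xstar(0, j);
      double xj_r = 0.0;
      for (int i = 0; i < n; ++i) xj_r += w[i] * xj[i] * r[i];
      const double z = xj_r + xtx[j] * beta[j];
      const double t = lambda * v[j];
      double bnew;
      if (t > 0.0) {
        if (z > t) bnew = (z - t) / xtx[j];
        else if (z < -t) bnew = (z + t) / xtx[j];
        else bnew = 0.0;
      } else {
        bnew = z / xtx[j];
      }
      const double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        beta[j] = bnew;
        const double sc = std::fabs(d) * std::sqrt(xtx[j]);
        if (sc > maxd) maxd = sc;
      }
    }
    if (maxd < tol) break;
  }
  return List::create(_["beta"] = beta, _["r"] = r, _["sweeps"] = sweeps);
}
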