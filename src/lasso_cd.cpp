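#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the lasso subproblem inside the graphical lasso:
//   minimize 0.5 * b' V b - s' b + lam * ||b||_1
// V symmetric positive definite. Warm-started via b. Active-set strategy:
// full sweeps alternate with sweeps over the current nonzero set.
// [[Rcpp::export(name = ".lasso_cd_cpp")]]
NumericVector lasso_cd_cpp(NumericMatrix V, NumericVector s, double lam,
                           NumericVector b_init, double tol = 1e-10,
                           int max_sweeps = 10000) {
  int p = s.size();
  NumericVector b = clone(b_init);
  std::vector<double> Vb(p, 0.0);
  for (int j = 0; j < p; ++j) {
    if (b[j] != 0.0) {
      double bj = b[j];
      for (int i = 0; i < p; ++i) Vb[i] += V(i, j) * bj;
    }
  }
  int it = 0;
  bool full = true;
  while (it < max_sweeps) {
    double delta_max = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full && b[j] == 0.0) continue;
      double bj_old = b[j];
      double g = s[j] - Vb[j] + V(j, j) * bj_old;
      double bj_new = 0.0;
      if (g > lam) bj_new = (g - lam) / V(j, j);
      else if (g < -lam) bj_new = (g + lam) / V(j, j);
      if (bj_new != bj_old) {
        double d = bj_new - bj_old;
        for (int i = 0; i < p; ++i) Vb[i] += V(i, j) * d;
        b[j] = bj_new;
        double ad = d < 0 ? -d : d;
        if (ad > delta_max) delta_max = ad;
      }
    }
    ++it;
    if (delta_max < tol) {
      if (full) break;   // converged on a full sweep
      full = true;       // active set stable; verify with a full sweep
    } else {
      full = false;      // keep iterating on the active set
    }
  }
  return b;
}
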