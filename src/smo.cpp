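#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solver (SMO with maximal-violating-pair working-set
// selection). Solves
//   min_a  0.5 a' Q a - e' a,   Q_ij = y_i y_j K_ij
//   s.t.   y' a = 0,  0 <= a_i <= C
// and returns the dual variables, the bias of the decision function
// f(x) = sum_i a_i y_i K(x, x_i) + b, the dual objective
// sum_i a_i - 0.5 a' Q a, and the final KKT violation m(a) - M(a).
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-8, int max_iter = 100000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient Q a - e
  int iter = 0;
  double m = 0.0, M = 0.0;

  while (iter < max_iter) {
    m = -1e300; M = 1e300;
    int i_up = -1, i_low = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (up && v > m) { m = v; i_up = t; }
      if (lo && v < M) { M = v; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || m - M < tol) break;

    const int i = i_up, j = i_low;
    const double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    // step t moves alpha_i by y_i * t and alpha_j by -y_j * t
    double tlo, thi;
    const double lo_i = (y[i] > 0) ? -alpha[i] : alpha[i] - C;
    const double hi_i = (y[i] > 0) ? C - alpha[i] : alpha[i];
    const double lo_j = (y[j] > 0) ? alpha[j] - C : -alpha[j];
    const double hi_j = (y[j] > 0) ? alpha[j] : C - alpha[j];
    tlo = std::max(lo_i, lo_j);
    thi = std::min(hi_i, hi_j);
    double step;
    if (eta > 1e-12) {
      step = (m - M) / eta;
      if (step > thi) step = thi;
      if (step < tlo) step = tlo;
    } else {
      // linear objective in the step; coefficient is -(m - M) < 0
      step = thi;
    }
    if (step == 0.0) break;
    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    // clamp roundoff
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > C) alpha[j] = C;
    for (int l = 0; l < n; ++l) {
      G[l] += y[l] * step * (K(l, i) - K(l, j));
    }
    ++iter;
  }

  // recompute the violation at the final iterate
  m = -1e300; M = 1e300;
  bool any_up = false, any_lo = false;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    const bool lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
    if (up) { any_up = true; if (v > m) m = v; }
    if (lo) { any_lo = true; if (v < M) M = v; }
  }

  // bias from free support vectors, else midpoint of the violation bounds
  double b = 0.0;
  int nfree = 0;
  const double eps_box = 1e-10 * (C > 1 ? C : 1.0);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > eps_box && alpha[t] < C - eps_box) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else if (any_up && any_lo) {
    b = (m + M) / 2.0;
  }

  double sum_a = 0.0, aG = 0.0;
  for (int t = 0; t < n; ++t) { sum_a += alpha[t]; aG += alpha[t] * G[t]; }
  const double objective = 0.5 * sum_a - 0.5 * aG;
  const double kkt = (any_up && any_lo) ? (m - M > 0 ? m - M : 0.0) : 0.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["objective"] = objective,
                      _["kkt_violation"] = kkt,
                      _["iterations"] = iter);
}
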