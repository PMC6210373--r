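#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian RBF Gram matrix K[i,j] = exp(-||x_i - y_j||^2 / (2 sigma^2)).
// [[Rcpp::export]]
NumericMatrix rbf_kernel_matrix_cpp(NumericMatrix X, NumericMatrix Y,
                                    double sigma) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  const double denom = 2.0 * sigma * sigma;
  NumericMatrix K(n, m);
  const double* xp = X.begin();
  const double* yp = Y.begin();
  double* kp = K.begin();
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = xp[i + (size_t)t * n] - yp[j + (size_t)t * m];
        s += diff * diff;
      }
      kp[i + (size_t)j * n] = std::exp(-s / denom);
    }
  }
  return K;
}

// SMO solver for the C-SVC dual:
//   min_a 0.5 a' Q a - 1' a,  Q_ij = y_i y_j K_ij,
//   s.t. y' a = 0, 0 <= a_i <= C.
// Working-set selection is the maximal-violating pair on the gradient;
// each two-variable subproblem is solved in closed form, so y' a = 0 is
// maintained exactly from the feasible start a = 0.  Convergence is
// declared when the violation gap m(a) - M(a) drops below tol.
// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                   int max_iter) {
  const int n = K.nrow();
  const double* kp = K.begin();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual at alpha = 0
  const double bound_eps = 1e-12;
  int iter = 0;
  double m_val = 0.0, M_val = 0.0;
  bool converged = false;

  while (iter < max_iter) {
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const double yt = yv[t], at = alpha[t];
      const double v = -yt * G[t];
      const bool up = (yt > 0) ? (at < C - bound_eps) : (at > bound_eps);
      const bool low = (yt > 0) ? (at > bound_eps) : (at < C - bound_eps);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    m_val = gmax;
    M_val = gmin;
    if (i < 0 || j < 0 || gmax - gmin <= tol) {
      converged = true;
      break;
    }

    // Feasible direction u: u_i = y_i, u_j = -y_j preserves y'a.
    const double* Ki = kp + (size_t)i * n;
    const double* Kj = kp + (size_t)j * n;
    double a_quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (a_quad <= 0.0) a_quad = 1e-12;
    double step = (gmax - gmin) / a_quad;
    const double lim_i = (yv[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double lim_j = (yv[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (step > lim_i) step = lim_i;
    if (step > lim_j) step = lim_j;

    const double d_i = yv[i] * step;
    const double d_j = -yv[j] * step;
    alpha[i] += d_i;
    alpha[j] += d_j;
    const double ci = yv[i] * d_i, cj = yv[j] * d_j;
    for (int t = 0; t < n; ++t) {
      G[t] += yv[t] * (Ki[t] * ci + Kj[t] * cj);
    }
    ++iter;
  }

  // Bias from the KKT conditions: for a free support vector t,
  // y_t (g_t + b) = 1 with g_t = sum_s alpha_s y_s K_ts, i.e.
  // b = y_t - g_t = -y_t G_t.  Average over free SVs; if none are free
  // the bias is bracketed by [M, m] and the midpoint is used.
  double b_sum = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b_sum += -yv[t] * G[t];
      ++n_free;
    }
  }
  const double b = (n_free > 0) ? (b_sum / n_free) : (m_val + M_val) / 2.0;

  // Dual objective: with G = Qa - 1, 0.5 a'Qa - 1'a = 0.5 a'(G - 1).
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj *= 0.5;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj,
                      _["gap"] = m_val - M_val);
}
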