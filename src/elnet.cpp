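#include <Rcpp.h>
using namespace Rcpp;

// Weighted elastic-net objective:
//   f(beta) = 1/2 sum_i w_i (y_i - x_i' beta)^2
//           + lambda * ( mixing * sum_j |beta_j|
//                      + (1 - mixing)/2 * sum_j beta_j^2 )
// Coordinate descent on the Gram ("covariance") form: with
//   G = X' W X  and  q = X' W y
// the partial residual correlation for coordinate j is
//   z_j = q_j - (G beta)_j + G_jj beta_j
// and each update costs O(p). Active-set sweeps (iterate the nonzero set
// to convergence, then one full sweep to confirm) follow the usual
// lasso-path practice.

static double soft_threshold(double z, double gamma) {
  if (z > gamma) return z - gamma;
  if (z < -gamma) return z + gamma;
  return 0.0;
}

static double objective(const NumericMatrix& X, const NumericVector& y,
                        const NumericVector& w, const NumericVector& beta,
                        double lambda, double mixing) {
  int n = X.nrow(), p = X.ncol();
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) fit += X(i, j) * beta[j];
    double r = y[i] - fit;
    rss += w[i] * r * r;
  }
  double l1 = 0.0, l2 = 0.0;
  for (int j = 0; j < p; ++j) {
    l1 += std::abs(beta[j]);
    l2 += beta[j] * beta[j];
  }
  return 0.5 * rss + lambda * (mixing * l1 + 0.5 * (1.0 - mixing) * l2);
}

// One coordinate-descent pass over the coordinates listed in `order`;
// returns the largest absolute coefficient change.
static double cd_pass(const std::vector<double>& G,
                      const std::vector<double>& q,
                      std::vector<double>& s, // s = G beta, kept in sync
                      std::vector<double>& beta,
                      const std::vector<int>& order,
                      int p, double lambda, double mixing) {
  double max_delta = 0.0;
  for (int idx : order) {
    int j = idx;
    double gjj = G[(size_t)j * p + j];
    double z = q[j] - s[j] + gjj * beta[j];
    double denom = gjj + lambda * (1.0 - mixing);
    double bnew = (denom <= 0.0) ? 0.0
      : soft_threshold(z, lambda * mixing) / denom;
    double delta = bnew - beta[j];
    if (delta != 0.0) {
      const double* Gj = &G[(size_t)j * p];
      for (int k = 0; k < p; ++k) s[k] += delta * Gj[k];
      beta[j] = bnew;
      double ad = std::abs(delta);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

// Fit one lambda from a warm start on precomputed G, q.
// Returns sweeps used, or -1 on non-convergence.
static int cd_fit(const std::vector<double>& G, const std::vector<double>& q,
                  std::vector<double>& beta, std::vector<double>& s,
                  int p, double lambda, double mixing, double tol,
                  int max_iter) {
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int used = 0;
  while (used < max_iter) {
    // full sweep
    double d = cd_pass(G, q, s, beta, all, p, lambda, mixing);
    ++used;
    if (d < tol) return used;
    // active-set sweeps until the active coordinates stabilise
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (used < max_iter) {
      double da = cd_pass(G, q, s, beta, active, p, lambda, mixing);
      ++used;
      if (da < tol) break;
    }
  }
  return -1;
}

static void gram(const NumericMatrix& X, const NumericVector& y,
                 const NumericVector& w, std::vector<double>& G,
                 std::vector<double>& q) {
  int n = X.nrow(), p = X.ncol();
  G.assign((size_t)p * p, 0.0);
  q.assign(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double qs = 0.0;
    for (int i = 0; i < n; ++i) qs += w[i] * xj[i] * y[i];
    q[j] = qs;
    for (int k = j; k < p; ++k) {
      const double* xk = &X(0, k);
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += w[i] * xj[i] * xk[i];
      G[(size_t)j * p + k] = g;
      G[(size_t)k * p + j] = g;
    }
  }
}

// [[Rcpp::export(name = ".elnet_fit_cpp")]]
List elnet_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                   double lambda, double mixing, NumericVector beta0,
                   double tol, int max_iter, bool trace) {
  int p = X.ncol();
  std::vector<double> G, q;
  gram(X, y, w, G, q);
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> s(p, 0.0);
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0)
      for (int k = 0; k < p; ++k) s[k] += beta[j] * G[(size_t)j * p + k];

  std::vector<double> obj_trace;
  int used;
  if (trace) {
    // sweep-by-sweep objective recording (diagnostic path, full sweeps)
    std::vector<int> all(p);
    for (int j = 0; j < p; ++j) all[j] = j;
    used = -1;
    NumericVector bcur(p);
    for (int it = 0; it < max_iter; ++it) {
      double d = cd_pass(G, q, s, beta, all, p, lambda, mixing);
      for (int j = 0; j < p; ++j) bcur[j] = beta[j];
      obj_trace.push_back(objective(X, y, w, bcur, lambda, mixing));
      if (d < tol) { used = it + 1; break; }
    }
  } else {
    used = cd_fit(G, q, beta, s, p, lambda, mixing, tol, max_iter);
  }

  return List::create(_["beta"] = wrap(beta),
                      _["converged"] = used >= 0,
                      _["iterations"] = used,
                      _["objective_trace"] = wrap(obj_trace));
}

// Path fit over a decreasing lambda sequence with warm starts.
// [[Rcpp::export(name = ".elnet_path_cpp")]]
List elnet_path_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                    NumericVector lambdas, double mixing,
                    double tol, int max_iter) {
  int p = X.ncol(), nl = lambdas.size();
  std::vector<double> G, q;
  gram(X, y, w, G, q);
  NumericMatrix coefs(p, nl);
  LogicalVector conv(nl);
  std::vector<double> beta(p, 0.0), s(p, 0.0);
  for (int k = 0; k < nl; ++k) {
    int used = cd_fit(G, q, beta, s, p, lambdas[k], mixing, tol, max_iter);
    conv[k] = used >= 0;
    for (int j = 0; j < p; ++j) coefs(j, k) = beta[j];
  }
  return List::create(_["coefficients"] = coefs, _["converged"] = conv);
}

// [[Rcpp::export(name = ".elnet_objective_cpp")]]
double elnet_objective_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                           NumericVector beta, double lambda, double mixing) {
  return objective(X, y, w, beta, lambda, mixing);
}
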