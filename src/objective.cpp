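#include <Rcpp.h>
using namespace Rcpp;

// Penalized WQS objective and analytic gradient for one or two indices.
//
// Parameter vector layout (length 1 + n_idx + n_idx*c + p):
//   beta0, beta1 (positive index) [, beta1n (negative index)],
//   v_pos (c) [, v_neg (c)], phi (p)
//
// Weights are w = v^2 / sum(v^2): the simplex constraint is built into the
// parameterization, so the optimizer works on unconstrained v.
//
// The L1 penalty is evaluated on the unit-normalized v (equivalently
// lambda * sum(sqrt(w))). During optimization it is smoothed as
// sqrt(w + eps) so the objective is differentiable at w = 0; eps = 0 gives
// the exact penalty. The objective is invariant to rescaling v, which the
// raw printed form lambda*sum(|v|) is not.

static void compute_index(const NumericMatrix& Q, const double* v, int c,
                          std::vector<double>& idx, double& s) {
  int n = Q.nrow();
  s = 0.0;
  std::vector<double> v2(c);
  for (int k = 0; k < c; ++k) { v2[k] = v[k] * v[k]; s += v2[k]; }
  std::fill(idx.begin(), idx.end(), 0.0);
  // column-major traversal: contiguous memory access
  const double* q = Q.begin();
  for (int k = 0; k < c; ++k) {
    double vk = v2[k];
    const double* col = q + (size_t)k * n;
    for (int j = 0; j < n; ++j) idx[j] += col[j] * vk;
  }
  double inv = 1.0 / s;
  for (int j = 0; j < n; ++j) idx[j] *= inv;
}

static double penalty_term(const double* v, int c, double s, double lambda,
                           double eps) {
  double pen = 0.0;
  for (int k = 0; k < c; ++k) pen += std::sqrt(v[k] * v[k] / s + eps);
  return lambda * pen;
}

// [[Rcpp::export]]
double wqs_objective_cpp(NumericVector theta, NumericVector y, NumericMatrix Q,
                         NumericMatrix Z, double lambda, bool two_index,
                         bool binomial, double eps = 1e-6) {
  int n = Q.nrow(), c = Q.ncol(), p = Z.ncol();
  int n_idx = two_index ? 2 : 1;
  const double* th = theta.begin();
  double beta0 = th[0];
  double b1p = th[1];
  double b1n = two_index ? th[2] : 0.0;
  const double* vp = th + 1 + n_idx;
  const double* vn = two_index ? th + 1 + n_idx + c : (const double*)0;
  const double* phi = th + 1 + n_idx + n_idx * c;

  std::vector<double> ip(n), in_(n);
  double sp, sn = 1.0;
  compute_index(Q, vp, c, ip, sp);
  if (two_index) compute_index(Q, vn, c, in_, sn);

  double loss = 0.0;
  for (int j = 0; j < n; ++j) {
    double eta = beta0 + b1p * ip[j];
    if (two_index) eta += b1n * in_[j];
    for (int m = 0; m < p; ++m) eta += Z(j, m) * phi[m];
    if (binomial) {
      // deviance contribution 2*(log(1+exp(eta)) - y*eta), stable form
      double lse = (eta > 0) ? eta + std::log1p(std::exp(-eta))
                             : std::log1p(std::exp(eta));
      loss += 2.0 * (lse - y[j] * eta);
    } else {
      double r = y[j] - eta;
      loss += r * r;
    }
  }
  double pen = penalty_term(vp, c, sp, lambda, eps);
  if (two_index) pen += penalty_term(vn, c, sn, lambda, eps);
  return loss + pen;
}

// Fused objective + gradient: element 0 is the objective value, the rest
// is the gradient. One pass over the data per optimizer iteration.
// [[Rcpp::export]]
NumericVector wqs_objgrad_cpp(NumericVector theta, NumericVector y,
                              NumericMatrix Q, NumericMatrix Z, double lambda,
                              bool two_index, bool binomial, double eps = 1e-6) {
  int n = Q.nrow(), c = Q.ncol(), p = Z.ncol();
  int n_idx = two_index ? 2 : 1;
  const double* th = theta.begin();
  double beta0 = th[0];
  double b1p = th[1];
  double b1n = two_index ? th[2] : 0.0;
  const double* vp = th + 1 + n_idx;
  const double* vn = two_index ? th + 1 + n_idx + c : (const double*)0;
  const double* phi = th + 1 + n_idx + n_idx * c;

  std::vector<double> ip(n), in_(n);
  double sp, sn = 1.0;
  compute_index(Q, vp, c, ip, sp);
  if (two_index) compute_index(Q, vn, c, in_, sn);

  std::vector<double> g(n);
  double loss = 0.0, g_sum = 0.0, g_ip = 0.0, g_in = 0.0;
  for (int j = 0; j < n; ++j) {
    double eta = beta0 + b1p * ip[j];
    if (two_index) eta += b1n * in_[j];
    for (int m = 0; m < p; ++m) eta += Z(j, m) * phi[m];
    double mu;
    if (binomial) {
      double lse = (eta > 0) ? eta + std::log1p(std::exp(-eta))
                             : std::log1p(std::exp(eta));
      loss += 2.0 * (lse - y[j] * eta);
      mu = 1.0 / (1.0 + std::exp(-eta));
    } else {
      double r = y[j] - eta;
      loss += r * r;
      mu = eta;
    }
    g[j] = 2.0 * (mu - y[j]);
    g_sum += g[j];
    g_ip += g[j] * ip[j];
    if (two_index) g_in += g[j] * in_[j];
  }

  std::vector<double> Qtg(c, 0.0);
  const double* q = Q.begin();
  for (int k = 0; k < c; ++k) {
    const double* col = q + (size_t)k * n;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += col[j] * g[j];
    Qtg[k] = acc;
  }

  NumericVector out(1 + theta.size());
  double pen_total = 0.0;
  out[1] = g_sum;
  out[2] = g_ip;
  if (two_index) out[3] = g_in;
  for (int d = 0; d < n_idx; ++d) {
    const double* v = (d == 0) ? vp : vn;
    double s = (d == 0) ? sp : sn;
    double b1 = (d == 0) ? b1p : b1n;
    double gdotidx = (d == 0) ? g_ip : g_in;
    double sum_ratio = 0.0, pen = 0.0;
    for (int k = 0; k < c; ++k) {
      double a = v[k] * v[k] / s;
      double sq = std::sqrt(a + eps);
      sum_ratio += a / sq;
      pen += sq;
    }
    pen_total += lambda * pen;
    int off = 1 + 1 + n_idx + d * c;
    for (int k = 0; k < c; ++k) {
      double a = v[k] * v[k] / s;
      double loss_g = (2.0 * b1 * v[k] / s) * (Qtg[k] - gdotidx);
      double pen_g =
          lambda * (v[k] / (s * std::sqrt(a + eps)) - (v[k] / s) * sum_ratio);
      out[off + k] = loss_g + pen_g;
    }
  }
  int offp = 1 + 1 + n_idx + n_idx * c;
  for (int m = 0; m < p; ++m) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += Z(j, m) * g[j];
    out[offp + m] = acc;
  }
  out[0] = loss + pen_total;
  return out;
}

// [[Rcpp::export]]
NumericVector wqs_gradient_cpp(NumericVector theta, NumericVector y,
                               NumericMatrix Q, NumericMatrix Z, double lambda,
                               bool two_index, bool binomial, double eps = 1e-6) {
  int n = Q.nrow(), c = Q.ncol(), p = Z.ncol();
  int n_idx = two_index ? 2 : 1;
  const double* th = theta.begin();
  double beta0 = th[0];
  double b1p = th[1];
  double b1n = two_index ? th[2] : 0.0;
  const double* vp = th + 1 + n_idx;
  const double* vn = two_index ? th + 1 + n_idx + c : (const double*)0;
  const double* phi = th + 1 + n_idx + n_idx * c;

  std::vector<double> ip(n), in_(n);
  double sp, sn = 1.0;
  compute_index(Q, vp, c, ip, sp);
  if (two_index) compute_index(Q, vn, c, in_, sn);

  // g[j] = d loss / d eta_j = 2*(mu_j - y_j) for both links
  std::vector<double> g(n);
  double g_sum = 0.0, g_ip = 0.0, g_in = 0.0;
  for (int j = 0; j < n; ++j) {
    double eta = beta0 + b1p * ip[j];
    if (two_index) eta += b1n * in_[j];
    for (int m = 0; m < p; ++m) eta += Z(j, m) * phi[m];
    double mu = binomial ? 1.0 / (1.0 + std::exp(-eta)) : eta;
    g[j] = 2.0 * (mu - y[j]);
    g_sum += g[j];
    g_ip += g[j] * ip[j];
    if (two_index) g_in += g[j] * in_[j];
  }

  std::vector<double> Qtg(c, 0.0);
  const double* q = Q.begin();
  for (int k = 0; k < c; ++k) {
    const double* col = q + (size_t)k * n;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += col[j] * g[j];
    Qtg[k] = acc;
  }

  NumericVector grad(theta.size());
  grad[0] = g_sum;
  grad[1] = g_ip;
  if (two_index) grad[2] = g_in;

  // d eta_j / d v_k = b1 * (2 v_k / s) * (Q_jk - index_j)
  // penalty: d/dv_m [lambda*sum_k sqrt(v_k^2/s + eps)]
  //   = lambda*( v_m/(s*sqrt(a_m+eps)) - (v_m/s)*sum_k a_k/sqrt(a_k+eps) )
  for (int d = 0; d < n_idx; ++d) {
    const double* v = (d == 0) ? vp : vn;
    double s = (d == 0) ? sp : sn;
    double b1 = (d == 0) ? b1p : b1n;
    double gdotidx = (d == 0) ? g_ip : g_in;
    double sum_ratio = 0.0;
    for (int k = 0; k < c; ++k) {
      double a = v[k] * v[k] / s;
      sum_ratio += a / std::sqrt(a + eps);
    }
    int off = 1 + n_idx + d * c;
    for (int k = 0; k < c; ++k) {
      double a = v[k] * v[k] / s;
      double loss_g = (2.0 * b1 * v[k] / s) * (Qtg[k] - gdotidx);
      double pen_g =
          lambda * (v[k] / (s * std::sqrt(a + eps)) - (v[k] / s) * sum_ratio);
      grad[off + k] = loss_g + pen_g;
    }
  }

  int offp = 1 + n_idx + n_idx * c;
  for (int m = 0; m < p; ++m) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += Z(j, m) * g[j];
    grad[offp + m] = acc;
  }
  return grad;
}
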