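// Core numerics for the banded neural lasso: forward map over diagonal
// offsets with zero-padded boundaries, subgradient of the L1-penalized
// squared-error objective, the full-batch Adam loop with cosine decay,
// and cyclic coordinate descent for the elastic net baseline.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward map: f_j = sum_k sum_i phi_k( W(k,i) * z_{j, i+off(k)} + B(k,i) ),
// with z treated as 0 outside 1..p while the bias is still added and passed
// through phi_k.
static void band_forward_impl(const arma::mat& W, const arma::mat& B,
                              const arma::mat& Z, const LogicalVector& relu,
                              arma::vec& f) {
  const int n = Z.n_rows, p = Z.n_cols;
  const int K = W.n_rows, N = (K - 1) / 2;
  f.zeros(n);
  double* fp = f.memptr();
  for (int k = 0; k < K; ++k) {
    const int off = k - N;
    const bool is_relu = relu[k];
    for (int i = 0; i < p; ++i) {
      const double w = W(k, i), b = B(k, i);
      const int col = i + off;
      if (col >= 0 && col < p) {
        const double* zc = Z.colptr(col);
        if (is_relu) {
          for (int j = 0; j < n; ++j) {
            const double a = w * zc[j] + b;
            if (a > 0.0) fp[j] += a;
          }
        } else {
          for (int j = 0; j < n; ++j) fp[j] += w * zc[j] + b;
        }
      } else {
        const double c = is_relu ? (b > 0.0 ? b : 0.0) : b;
        for (int j = 0; j < n; ++j) fp[j] += c;
      }
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_band_forward(const arma::mat& W, const arma::mat& B,
                           const arma::mat& Z, const LogicalVector& relu) {
  arma::vec f;
  band_forward_impl(W, B, Z, relu, f);
  return f;
}

static inline double sgn(double x) { return (x > 0.0) - (x < 0.0); }

// Subgradient of  sum_j (y_j - f_j)^2 + lam * (sum|W| + sum|B|).
// ReLU derivative is 1 for positive pre-activation, 0 otherwise (0 at 0).
// Returns the objective at (W, B) alongside the gradient.
static double band_gradient_impl(const arma::mat& W, const arma::mat& B,
                                 const arma::mat& Z, const arma::vec& y,
                                 double lam, const LogicalVector& relu,
                                 arma::mat& dW, arma::mat& dB) {
  const int n = Z.n_rows, p = Z.n_cols;
  const int K = W.n_rows, N = (K - 1) / 2;
  arma::vec f;
  band_forward_impl(W, B, Z, relu, f);
  arma::vec r = 2.0 * (f - y);          // d(SSE)/df
  const double sse = arma::accu(arma::square(y - f));
  const double* rp = r.memptr();
  dW.set_size(K, p); dB.set_size(K, p);
  for (int k = 0; k < K; ++k) {
    const int off = k - N;
    const bool is_relu = relu[k];
    for (int i = 0; i < p; ++i) {
      const double w = W(k, i), b = B(k, i);
      double gw = 0.0, gb = 0.0;
      const int col = i + off;
      if (col >= 0 && col < p) {
        const double* zc = Z.colptr(col);
        if (is_relu) {
          for (int j = 0; j < n; ++j) {
            if (w * zc[j] + b > 0.0) { gw += rp[j] * zc[j]; gb += rp[j]; }
          }
        } else {
          for (int j = 0; j < n; ++j) { gw += rp[j] * zc[j]; gb += rp[j]; }
        }
      } else {
        // zero-padded boundary: the weight does not enter the forward map,
        // the bias does (through phi)
        if (!is_relu || b > 0.0) gb = arma::accu(r);
      }
      dW(k, i) = gw + lam * sgn(w);
      dB(k, i) = gb + lam * sgn(b);
    }
  }
  return sse + lam * (arma::accu(arma::abs(W)) + arma::accu(arma::abs(B)));
}

// [[Rcpp::export]]
List cpp_band_gradient(const arma::mat& W, const arma::mat& B,
                       const arma::mat& Z, const arma::vec& y,
                       double lam, const LogicalVector& relu) {
  arma::mat dW, dB;
  double obj = band_gradient_impl(W, B, Z, y, lam, relu, dW, dB);
  return List::create(_["dW"] = dW, _["dB"] = dB, _["objective"] = obj);
}

// Full-batch Adam on the banded objective, learning rate following a cosine
// schedule lr(s) = lr_end + 0.5 (lr_start - lr_end)(1 + cos(pi s / T)) with
// s = t - 1 for update t (the first update uses lr_start).
// loss_trace[t] is the objective at the parameters entering iteration t.
// [[Rcpp::export]]
List cpp_fit_adam(const arma::mat& Z, const arma::vec& y,
                  const LogicalVector& relu,
                  const arma::mat& W0, const arma::mat& B0,
                  int iterations, double lr_start, double lr_end,
                  double beta1, double beta2, double eps, double lam,
                  bool train_biases) {
  arma::mat W = W0, B = B0;
  arma::mat mW(arma::size(W), arma::fill::zeros), vW(arma::size(W), arma::fill::zeros);
  arma::mat mB(arma::size(B), arma::fill::zeros), vB(arma::size(B), arma::fill::zeros);
  arma::mat dW, dB;
  arma::vec trace(iterations);
  double b1t = 1.0, b2t = 1.0;
  for (int t = 1; t <= iterations; ++t) {
    const double obj = band_gradient_impl(W, B, Z, y, lam, relu, dW, dB);
    trace(t - 1) = obj;
    if (!std::isfinite(obj) || (t > 1 && obj > 1e12 * trace(0)))
      stop("objective diverged at iteration %d (value %g)", t, obj);
    const double s = double(t - 1) / double(iterations);
    const double lr = lr_end + 0.5 * (lr_start - lr_end) * (1.0 + std::cos(M_PI * s));
    b1t *= beta1; b2t *= beta2;
    const double c1 = 1.0 / (1.0 - b1t), c2 = 1.0 / (1.0 - b2t);
    mW = beta1 * mW + (1.0 - beta1) * dW;
    vW = beta2 * vW + (1.0 - beta2) * arma::square(dW);
    W -= lr * (c1 * mW) / (arma::sqrt(c2 * vW) + eps);
    if (train_biases) {
      mB = beta1 * mB + (1.0 - beta1) * dB;
      vB = beta2 * vB + (1.0 - beta2) * arma::square(dB);
      B -= lr * (c1 * mB) / (arma::sqrt(c2 * vB) + eps);
    }
  }
  return List::create(_["W"] = W, _["B"] = B, _["loss_trace"] = trace);
}

// Cyclic coordinate descent for
//   sum_i (y_i - b0 - z_i' w)^2 + lam * sum_j [ (1-alpha)/2 w_j^2 + alpha |w_j| ]
// with an unpenalized intercept handled by centering.
// [[Rcpp::export]]
List cpp_enet_cd(const arma::mat& Z, const arma::vec& y,
                 double lam, double alpha, double tol, int max_sweeps) {
  const int n = Z.n_rows, p = Z.n_cols;
  arma::rowvec zm = arma::mean(Z, 0);
  arma::mat Zc = Z.each_row() - zm;
  const double ym = arma::mean(y);
  arma::vec r = y - ym;                  // residual with w = 0
  arma::vec w(p, arma::fill::zeros);
  arma::vec ss(p);
  for (int j = 0; j < p; ++j) ss(j) = arma::dot(Zc.col(j), Zc.col(j));
  const double thr = lam * alpha;
  const double l2 = lam * (1.0 - alpha);
  int sweep = 0;
  bool converged = false;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double wj = w(j);
      if (wj != 0.0) r += Zc.col(j) * wj;
      const double rho = 2.0 * arma::dot(Zc.col(j), r);
      const double denom = 2.0 * ss(j) + l2;
      double wn = 0.0;
      if (denom > 0.0 && std::abs(rho) > thr)
        wn = sgn(rho) * (std::abs(rho) - thr) / denom;
      if (wn != 0.0) r -= Zc.col(j) * wn;
      w(j) = wn;
      const double d = std::abs(wn - wj);
      if (d > max_delta) max_delta = d;
    }
    if (max_delta < tol) { converged = true; ++sweep; break; }
  }
  const double intercept = ym - arma::dot(zm, w);
  return List::create(_["w"] = w, _["intercept"] = intercept,
                      _["sweeps"] = sweep, _["converged"] = converged);
}
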