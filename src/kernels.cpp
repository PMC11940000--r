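// Performance kernels for the 1-D convolutional EMG branch.
//
// Layout conventions match the R engine: an EMG batch is an array
// (batch, frames, channels) in R's column-major order; conv weights are
// (kernel_size * in_channels) x filters matrices whose row order is kernel
// position major, input channel minor. For each kernel offset k the slab of
// frames (t + k) is contiguous per channel, so the im2col block is assembled
// with memcpy and the convolution reduces to a dgemm per offset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".conv_relu_fwd_cpp")]]
NumericVector conv_relu_fwd_cpp(NumericVector X, NumericMatrix W,
                                NumericVector b, int K, bool relu) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], L = d[1], C = d[2];
  const int F = W.ncol();
  const int Lout = L - K + 1;
  const size_t n = (size_t)B * Lout;
  arma::mat Wm(W.begin(), W.nrow(), F, false, true);
  arma::mat Xk(n, C);
  arma::mat Y(n, F, arma::fill::zeros);
  const double* xp = X.begin();
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      std::memcpy(Xk.colptr(c), xp + (size_t)c * B * L + (size_t)k * B,
                  sizeof(double) * n);
    }
    Y += Xk * Wm.rows(k * C, (k + 1) * C - 1);
  }
  for (int f = 0; f < F; ++f) Y.col(f) += b[f];
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(B, Lout, F);
  return out;
}

// Backward through (optional ReLU o) valid conv1d. Y is the forward output
// (post-ReLU when relu = true); dY the gradient w.r.t. Y. Returns dW, db and
// (optionally) dX.
// [[Rcpp::export(name = ".conv_relu_bwd_cpp")]]
List conv_relu_bwd_cpp(NumericVector X, NumericVector Y, NumericVector dY,
                       NumericMatrix W, int K, bool relu, bool want_dx) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], L = d[1], C = d[2];
  const int F = W.ncol();
  const int Lout = L - K + 1;
  const size_t n = (size_t)B * Lout;
  arma::mat Wm(W.begin(), W.nrow(), F, false, true);
  arma::mat dYm(n, F);
  const double* yp = Y.begin();
  const double* dyp = dY.begin();
  const size_t total = n * F;
  if (relu) {
    for (size_t i = 0; i < total; ++i) dYm[i] = yp[i] > 0.0 ? dyp[i] : 0.0;
  } else {
    std::memcpy(dYm.memptr(), dyp, sizeof(double) * total);
  }
  arma::mat dW(K * C, F, arma::fill::zeros);
  arma::rowvec db = arma::sum(dYm, 0);
  const double* xp = X.begin();
  arma::mat Xk(n, C);
  NumericVector dX;
  double* dxp = nullptr;
  if (want_dx) {
    dX = NumericVector((size_t)B * L * C);
    dX.attr("dim") = IntegerVector::create(B, L, C);
    dxp = dX.begin();
  }
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      std::memcpy(Xk.colptr(c), xp + (size_t)c * B * L + (size_t)k * B,
                  sizeof(double) * n);
    }
    dW.rows(k * C, (k + 1) * C - 1) = Xk.t() * dYm;
    if (want_dx) {
      arma::mat dXc = dYm * Wm.rows(k * C, (k + 1) * C - 1).t();
      for (int c = 0; c < C; ++c) {
        double* dst = dxp + (size_t)c * B * L + (size_t)k * B;
        const double* src = dXc.colptr(c);
        for (size_t i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db),
                      _["dX"] = want_dx ? (SEXP)dX : R_NilValue);
}

// Non-overlapping max pooling along the frame axis; trailing remainder frames
// are dropped. Returns the pooled array and 0-based argmax offsets for the
// backward pass (ties to the earliest frame).
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector X, int size) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], L = d[1], F = d[2];
  const int Lp = L / size;
  NumericVector Y((size_t)B * Lp * F);
  IntegerVector idx((size_t)B * Lp * F);
  const double* xp = X.begin();
  double* yp = Y.begin();
  int* ip = idx.begin();
  for (int f = 0; f < F; ++f) {
    for (int lp = 0; lp < Lp; ++lp) {
      for (int b = 0; b < B; ++b) {
        size_t base = (size_t)f * B * L + (size_t)lp * size * B + b;
        double best = xp[base];
        int besti = 0;
        for (int i = 1; i < size; ++i) {
          double v = xp[base + (size_t)i * B];
          if (v > best) { best = v; besti = i; }
        }
        size_t o = (size_t)f * B * Lp + (size_t)lp * B + b;
        yp[o] = best;
        ip[o] = besti;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(B, Lp, F);
  idx.attr("dim") = IntegerVector::create(B, Lp, F);
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dY, int L,
                              int size) {
  IntegerVector d = dY.attr("dim");
  const int B = d[0], Lp = d[1], F = d[2];
  NumericVector dX((size_t)B * L * F);
  dX.attr("dim") = IntegerVector::create(B, L, F);
  const double* dyp = dY.begin();
  const int* ip = idx.begin();
  double* dxp = dX.begin();
  for (int f = 0; f < F; ++f) {
    for (int lp = 0; lp < Lp; ++lp) {
      for (int b = 0; b < B; ++b) {
        size_t o = (size_t)f * B * Lp + (size_t)lp * B + b;
        size_t dst = (size_t)f * B * L + ((size_t)lp * size + ip[o]) * B + b;
        dxp[dst] += dyp[o];
      }
    }
  }
  return dX;
}

// Per-channel FIR smoothing with mirror (no edge repeat) padding; used by the
// Gaussian envelope smoother. The kernel is symmetric so correlation equals
// convolution.
// [[Rcpp::export(name = ".fir_reflect_cpp")]]
NumericMatrix fir_reflect_cpp(NumericMatrix x, NumericVector k) {
  const int C = x.nrow(), L = x.ncol(), K = k.size();
  const int half = (K - 1) / 2;
  NumericMatrix out(C, L);
  std::vector<double> pad((size_t)L + 2 * half);
  std::vector<double> kk(k.begin(), k.end());
  const double* kp = kk.data();
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < L + 2 * half; ++i) {
      int t = i - half;
      if (L == 1) {
        t = 0;
      } else {
        while (t < 0 || t >= L) {
          if (t < 0) t = -t;
          if (t >= L) t = 2 * (L - 1) - t;
        }
      }
      pad[i] = x(c, t);
    }
    const double* pp = pad.data();
    for (int t = 0; t < L; ++t) {
      double s = 0.0;
      const double* p = pp + t;
      for (int j = 0; j < K; ++j) s += p[j] * kp[j];
      out(c, t) = s;
    }
  }
  return out;
}

// Direct-form-II-transposed IIR filter, zero initial conditions (the one-way
// pass); coefficients normalized by a[0].
static void iir_pass(const std::vector<double>& bb, const std::vector<double>& aa,
                     const double* x, double* y, int n) {
  const int ns = (int)bb.size() - 1;
  std::vector<double> s(ns, 0.0);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + (ns > 0 ? s[0] : 0.0);
    for (int j = 0; j + 1 < ns; ++j) s[j] = s[j + 1] + bb[j + 1] * xt - aa[j + 1] * yt;
    if (ns > 0) s[ns - 1] = bb[ns] * xt - aa[ns] * yt;
    y[t] = yt;
  }
}

// Per-channel IIR filtering of a channels x frames matrix. With zero_phase,
// applies the filter forward and (after appending 2*max(len(a), len(b))
// zeros so the forward transient rings out) backward, then trims -- the
// conventional forward-backward scheme.
// [[Rcpp::export(name = ".iir_mat_cpp")]]
NumericMatrix iir_mat_cpp(NumericVector b, NumericVector a, NumericMatrix x,
                          bool zero_phase) {
  const int C = x.nrow(), L = x.ncol();
  const int nw = std::max(b.size(), a.size());
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;
  NumericMatrix out(C, L);
  const int pad = zero_phase ? 2 * nw : 0;
  std::vector<double> xin(L + pad), yout(L + pad);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < L; ++t) xin[t] = x(c, t);
    std::fill(xin.begin() + L, xin.end(), 0.0);
    iir_pass(bb, aa, xin.data(), yout.data(), L + pad);
    if (zero_phase) {
      std::reverse(yout.begin(), yout.end());
      iir_pass(bb, aa, yout.data(), xin.data(), L + pad);
      std::reverse(xin.begin(), xin.end());
      for (int t = 0; t < L; ++t) out(c, t) = xin[t];
    } else {
      for (int t = 0; t < L; ++t) out(c, t) = yout[t];
    }
  }
  return out;
}
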