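// Convolution primitives for the GAN layers.
//
// Feature maps are stored as (H*W*N) x C matrices, rows ordered with h
// fastest, then w, then batch index n (column-major spatial flattening).
// Kernels are (k*k*Cin) x Cout with patch entries ordered kh, kw, cin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Valid output range [lo, hi) for one kernel offset: positions o with
// 0 <= o*s - p + koff < L.
static inline void valid_range(int L, int Lo, int s, int p, int koff,
                               int* lo, int* hi) {
  int l = 0;
  while (l < Lo && l * s - p + koff < 0) ++l;
  int h = Lo;
  while (h > l && (h - 1) * s - p + koff >= L) --h;
  *lo = l;
  *hi = h;
}

static arma::mat im2col(const arma::mat& X, int H, int W, int N,
                        int k, int s, int p, int Ho, int Wo) {
  const int Cin = X.n_cols;
  arma::mat P(static_cast<arma::uword>(Ho) * Wo * N, k * k * Cin,
              arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi;
      valid_range(W, Wo, s, p, kw, &wlo, &whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi;
        valid_range(H, Ho, s, p, kh, &hlo, &hhi);
        const int hn = hhi - hlo;
        if (hn <= 0) continue;
        double* pc = P.colptr(kh + k * kw + k * k * c);
        for (int n = 0; n < N; ++n) {
          for (int wo = wlo; wo < whi; ++wo) {
            const int wi = wo * s - p + kw;
            double* pd = pc + static_cast<arma::uword>(n) * Ho * Wo +
                         static_cast<arma::uword>(wo) * Ho + hlo;
            const double* ps = xc + static_cast<arma::uword>(n) * H * W +
                               static_cast<arma::uword>(wi) * H +
                               (hlo * s - p + kh);
            if (s == 1) {
              std::memcpy(pd, ps, hn * sizeof(double));
            } else {
              for (int i = 0; i < hn; ++i) pd[i] = ps[i * s];
            }
          }
        }
      }
    }
  }
  return P;
}

static void col2im_acc(arma::mat& dX, const arma::mat& dP, int H, int W,
                       int N, int k, int s, int p, int Ho, int Wo) {
  const int Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi;
      valid_range(W, Wo, s, p, kw, &wlo, &whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi;
        valid_range(H, Ho, s, p, kh, &hlo, &hhi);
        const int hn = hhi - hlo;
        if (hn <= 0) continue;
        const double* pc = dP.colptr(kh + k * kw + k * k * c);
        for (int n = 0; n < N; ++n) {
          for (int wo = wlo; wo < whi; ++wo) {
            const int wi = wo * s - p + kw;
            const double* ps = pc + static_cast<arma::uword>(n) * Ho * Wo +
                               static_cast<arma::uword>(wo) * Ho + hlo;
            double* pd = xc + static_cast<arma::uword>(n) * H * W +
                         static_cast<arma::uword>(wi) * H +
                         (hlo * s - p + kh);
            if (s == 1) {
              for (int i = 0; i < hn; ++i) pd[i] += ps[i];
            } else {
              for (int i = 0; i < hn; ++i) pd[i * s] += ps[i];
            }
          }
        }
      }
    }
  }
}

// Direct convolution (no patch matrix): per-image accumulation over
// contiguous h-runs. Wins for large spatial extents with few channels,
// where the im2col matrix would be allocation-bound.
// [[Rcpp::export]]
arma::mat conv2d_fwd_direct(const arma::mat& X, const arma::mat& Wt,
                            const arma::vec& b, int H, int W, int N,
                            int k, int s, int p) {
  const int Cin = X.n_cols, Cout = Wt.n_cols;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  arma::mat Y(static_cast<arma::uword>(Ho) * Wo * N, Cout);
  for (int co = 0; co < Cout; ++co)
    Y.col(co).fill(b(co));
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci) + static_cast<arma::uword>(n) * H * W;
      for (int co = 0; co < Cout; ++co) {
        double* yc = Y.colptr(co) + static_cast<arma::uword>(n) * Ho * Wo;
        for (int kw = 0; kw < k; ++kw) {
          int wlo, whi;
          valid_range(W, Wo, s, p, kw, &wlo, &whi);
          for (int kh = 0; kh < k; ++kh) {
            int hlo, hhi;
            valid_range(H, Ho, s, p, kh, &hlo, &hhi);
            const int hn = hhi - hlo;
            if (hn <= 0) continue;
            const double w = Wt(kh + k * kw + k * k * ci, co);
            for (int wo = wlo; wo < whi; ++wo) {
              double* pd = yc + static_cast<arma::uword>(wo) * Ho + hlo;
              const double* ps = xc +
                  static_cast<arma::uword>(wo * s - p + kw) * H +
                  (hlo * s - p + kh);
              if (s == 1) {
                for (int i = 0; i < hn; ++i) pd[i] += w * ps[i];
              } else {
                for (int i = 0; i < hn; ++i) pd[i] += w * ps[i * s];
              }
            }
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv2d_bwd_direct(const arma::mat& X, const arma::mat& Wt,
                       const arma::mat& dY, int H, int W, int N,
                       int k, int s, int p) {
  const int Cin = X.n_cols, Cout = Wt.n_cols;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  arma::mat dX(X.n_rows, Cin, arma::fill::zeros);
  arma::mat dW(Wt.n_rows, Cout, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 0).t();
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci) + static_cast<arma::uword>(n) * H * W;
      double* dxc = dX.colptr(ci) + static_cast<arma::uword>(n) * H * W;
      for (int co = 0; co < Cout; ++co) {
        const double* dyc = dY.colptr(co) +
                            static_cast<arma::uword>(n) * Ho * Wo;
        for (int kw = 0; kw < k; ++kw) {
          int wlo, whi;
          valid_range(W, Wo, s, p, kw, &wlo, &whi);
          for (int kh = 0; kh < k; ++kh) {
            int hlo, hhi;
            valid_range(H, Ho, s, p, kh, &hlo, &hhi);
            const int hn = hhi - hlo;
            if (hn <= 0) continue;
            const arma::uword widx = kh + k * kw + k * k * ci;
            const double w = Wt(widx, co);
            double dw = 0.0;
            for (int wo = wlo; wo < whi; ++wo) {
              const double* pg = dyc + static_cast<arma::uword>(wo) * Ho + hlo;
              const arma::uword xoff =
                  static_cast<arma::uword>(wo * s - p + kw) * H +
                  (hlo * s - p + kh);
              const double* ps = xc + xoff;
              double* pd = dxc + xoff;
              if (s == 1) {
                for (int i = 0; i < hn; ++i) {
                  dw += pg[i] * ps[i];
                  pd[i] += w * pg[i];
                }
              } else {
                for (int i = 0; i < hn; ++i) {
                  dw += pg[i] * ps[i * s];
                  pd[i * s] += w * pg[i];
                }
              }
            }
            dW(widx, co) += dw;
          }
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// Forward pass; also returns the im2col patch matrix (as an external
// pointer, avoiding a copy) so the backward pass does not rebuild it.
// [[Rcpp::export]]
List conv2d_fwd(const arma::mat& X, const arma::mat& Wt,
                const arma::vec& b, int H, int W, int N,
                int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  XPtr<arma::mat> P(new arma::mat(im2col(X, H, W, N, k, s, p, Ho, Wo)));
  arma::mat Y = (*P) * Wt;
  Y.each_row() += b.t();
  return List::create(Named("Y") = Y, Named("P") = P);
}

// [[Rcpp::export]]
List conv2d_bwd(SEXP Pptr, const arma::mat& Wt, const arma::mat& dY,
                int H, int W, int N, int Cin,
                int k, int s, int p) {
  XPtr<arma::mat> P(Pptr);
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  arma::mat dW = P->t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dP = dY * Wt.t();
  arma::mat dX(static_cast<arma::uword>(H) * W * N, Cin, arma::fill::zeros);
  col2im_acc(dX, dP, H, W, N, k, s, p, Ho, Wo);
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// ---- cheap elementwise / normalization helpers ---------------------------

// [[Rcpp::export]]
arma::mat relu_fwd(const arma::mat& X) {
  arma::mat Y = X;
  Y.transform([](double v) { return v > 0 ? v : 0.0; });
  return Y;
}

// dX = dY where the forward output was positive.
// [[Rcpp::export]]
arma::mat relu_bwd(const arma::mat& Y, const arma::mat& dY) {
  arma::mat dX(Y.n_rows, Y.n_cols);
  const double* y = Y.memptr();
  const double* g = dY.memptr();
  double* o = dX.memptr();
  const arma::uword n = Y.n_elem;
  for (arma::uword i = 0; i < n; ++i) o[i] = y[i] > 0 ? g[i] : 0.0;
  return dX;
}

// [[Rcpp::export]]
arma::mat lrelu_fwd(const arma::mat& X, double alpha) {
  arma::mat Y = X;
  Y.transform([alpha](double v) { return v > 0 ? v : alpha * v; });
  return Y;
}

// [[Rcpp::export]]
arma::mat lrelu_bwd(const arma::mat& Y, const arma::mat& dY, double alpha) {
  arma::mat dX(Y.n_rows, Y.n_cols);
  const double* y = Y.memptr();
  const double* g = dY.memptr();
  double* o = dX.memptr();
  const arma::uword n = Y.n_elem;
  for (arma::uword i = 0; i < n; ++i) o[i] = y[i] > 0 ? g[i] : alpha * g[i];
  return dX;
}

// Batchnorm forward over columns; returns Y, xhat, mean, invstd.
// [[Rcpp::export]]
List bn_fwd_cpp(const arma::mat& X, const arma::vec& g, const arma::vec& B,
                const arma::vec& mu, const arma::vec& invstd) {
  const arma::uword C = X.n_cols, n = X.n_rows;
  arma::mat Y(n, C), xhat(n, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double m = mu(c), is = invstd(c), gc = g(c), bc = B(c);
    const double* x = X.colptr(c);
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    for (arma::uword i = 0; i < n; ++i) {
      const double v = (x[i] - m) * is;
      xh[i] = v;
      y[i] = gc * v + bc;
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = xhat);
}

// Batchnorm backward (training mode, batch statistics).
// [[Rcpp::export]]
List bn_bwd_cpp(const arma::mat& xhat, const arma::mat& dY,
                const arma::vec& g, const arma::vec& invstd) {
  const arma::uword C = xhat.n_cols, n = xhat.n_rows;
  arma::mat dX(n, C);
  arma::vec dg(C), dB(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xh = xhat.colptr(c);
    const double* dy = dY.colptr(c);
    double sdy = 0, sdyx = 0;
    for (arma::uword i = 0; i < n; ++i) {
      sdy += dy[i];
      sdyx += dy[i] * xh[i];
    }
    dg(c) = sdyx;
    dB(c) = sdy;
    const double mdy = sdy / n, mdyx = sdyx / n;
    const double a = g(c) * invstd(c);
    double* o = dX.colptr(c);
    for (arma::uword i = 0; i < n; ++i)
      o[i] = a * (dy[i] - mdy - xh[i] * mdyx);
  }
  return List::create(Named("dX") = dX, Named("dg") = dg, Named("dB") = dB);
}
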