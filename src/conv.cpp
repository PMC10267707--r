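// Compiled kernels for the batched network passes.
//
// Activation layout everywhere: array (h, w, B, C) flattened column-major.
// Expanded weight matrix Wx: (C * k * k) x Cout, patch rows slice-major
// with the k x k offsets column-major within each block, matching the
// R-side expansion tables.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2colInto(double *p, const double *x, int h, int w, int B,
                       int C, int k) {
  const int oh = h - k + 1, ow = w - k + 1;
  const std::size_t n = (std::size_t)oh * ow * B;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int col = c * k * k + b * k + a;
        double *dst = p + (std::size_t)col * n;
        for (int bb = 0; bb < B; ++bb)
          for (int j = 0; j < ow; ++j) {
            const double *src = x + a + (std::size_t)(b + j) * h +
                                (std::size_t)bb * h * w +
                                (std::size_t)c * h * w * B;
            std::memcpy(dst, src, oh * sizeof(double));
            dst += oh;
          }
      }
}

// forward pass of one conv layer; optionally hands the patch matrix back
// so the backward pass can reuse it
// [[Rcpp::export(name = ".convForwardC")]]
List convForwardC(const NumericVector &X, const NumericMatrix &Wx, int h,
                  int w, int B, int C, int k, bool keepPatches) {
  const int oh = h - k + 1, ow = w - k + 1;
  const arma::uword n = (arma::uword)oh * ow * B;
  NumericMatrix Pout(n, (R_xlen_t)C * k * k);
  arma::mat P(REAL(Pout), n, (arma::uword)C * k * k, false, true);
  im2colInto(REAL(Pout), REAL(X), h, w, B, C, k);
  const arma::mat W(const_cast<double *>(REAL(Wx)), Wx.nrow(), Wx.ncol(),
                    false, true);
  NumericMatrix Y(n, W.n_cols);
  arma::mat Ym(REAL(Y), n, W.n_cols, false, true);
  Ym = P * W;
  if (keepPatches)
    return List::create(_["Y"] = Y, _["P"] = Pout);
  return List::create(_["Y"] = Y);
}

// backward pass given the cached patch matrix
// [[Rcpp::export(name = ".convBackwardC")]]
List convBackwardC(const NumericMatrix &P, const NumericMatrix &Wx,
                   const NumericMatrix &dY, int h, int w, int B, int C,
                   int k, bool needInput) {
  const arma::mat Pm(const_cast<double *>(REAL(P)), P.nrow(), P.ncol(),
                     false, true);
  const arma::mat W(const_cast<double *>(REAL(Wx)), Wx.nrow(), Wx.ncol(),
                    false, true);
  const arma::mat dYm(const_cast<double *>(REAL(dY)), dY.nrow(), dY.ncol(),
                      false, true);
  NumericMatrix dWx(Wx.nrow(), Wx.ncol());
  arma::mat dWm(REAL(dWx), Wx.nrow(), Wx.ncol(), false, true);
  dWm = Pm.t() * dYm;
  if (!needInput)
    return List::create(_["dWx"] = dWx);
  arma::mat dP = dYm * W.t();
  NumericVector dX((R_xlen_t)h * w * B * C);
  double *x = REAL(dX);
  const int oh = h - k + 1, ow = w - k + 1;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int col = c * k * k + b * k + a;
        const double *src = dP.colptr(col);
        for (int bb = 0; bb < B; ++bb)
          for (int j = 0; j < ow; ++j) {
            double *dst = x + a + (std::size_t)(b + j) * h +
                          (std::size_t)bb * h * w +
                          (std::size_t)c * h * w * B;
            for (int i = 0; i < oh; ++i) dst[i] += src[i];
            src += oh;
          }
      }
  return List::create(_["dWx"] = dWx, _["dX"] = dX);
}

// batch norm forward over an (n x C) view; per-column statistics
// [[Rcpp::export(name = ".bnForwardC")]]
List bnForwardC(const NumericVector &X, int n, int C, NumericVector gamma,
                NumericVector beta, NumericVector runMean,
                NumericVector runVar, bool training, double momentum,
                double eps) {
  NumericVector Y((R_xlen_t)n * C), xhat((R_xlen_t)n * C), iv(C);
  NumericVector rm = clone(runMean), rv = clone(runVar);
  const double *x = REAL(X);
  double *y = REAL(Y), *xh = REAL(xhat);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (std::size_t)c * n;
    double *yc = y + (std::size_t)c * n, *hc = xh + (std::size_t)c * n;
    double mu, va;
    if (training) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += xc[i];
      mu = s / n;
      double q = 0;
      for (int i = 0; i < n; ++i) {
        const double d = xc[i] - mu;
        q += d * d;
      }
      va = q / n;
      rm[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv[c] = (1 - momentum) * rv[c] + momentum * va;
    } else {
      mu = rm[c];
      va = rv[c];
    }
    const double ivc = 1.0 / std::sqrt(va + eps);
    iv[c] = ivc;
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * ivc;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["iv"] = iv,
                      _["runMean"] = rm, _["runVar"] = rv);
}

// [[Rcpp::export(name = ".bnBackwardC")]]
List bnBackwardC(const NumericVector &dY, const NumericVector &xhat, int n,
                 int C, NumericVector gamma, NumericVector iv,
                 bool training) {
  NumericVector dX((R_xlen_t)n * C), dGamma(C), dBeta(C);
  const double *dy = REAL(dY), *xh = REAL(xhat);
  double *dx = REAL(dX);
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy + (std::size_t)c * n;
    const double *hc = xh + (std::size_t)c * n;
    double *dxc = dx + (std::size_t)c * n;
    double sb = 0, sg = 0;
    for (int i = 0; i < n; ++i) {
      sb += dyc[i];
      sg += dyc[i] * hc[i];
    }
    dGamma[c] = sg;
    dBeta[c] = sb;
    const double s = gamma[c] * iv[c];
    if (training) {
      const double m1 = sb / n, m2 = sg / n;
      for (int i = 0; i < n; ++i)
        dxc[i] = (dyc[i] - m1 - hc[i] * m2) * s;
    } else {
      for (int i = 0; i < n; ++i) dxc[i] = dyc[i] * s;
    }
  }
  return List::create(_["dX"] = dX, _["dGamma"] = dGamma,
                      _["dBeta"] = dBeta);
}

// relu with mask for backward
// [[Rcpp::export(name = ".reluForwardC")]]
List reluForwardC(const NumericVector &X) {
  R_xlen_t n = X.size();
  NumericVector Y(n);
  LogicalVector M(n);
  const double *x = REAL(X);
  double *y = REAL(Y);
  int *m = LOGICAL(M);
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool pos = x[i] > 0;
    m[i] = pos;
    y[i] = pos ? x[i] : 0.0;
  }
  return List::create(_["Y"] = Y, _["M"] = M);
}

// 2x1 max pool over the height axis; drops a trailing odd row
// [[Rcpp::export(name = ".pool2x1ForwardC")]]
List pool2x1ForwardC(const NumericVector &X, int h, int rest) {
  const int hp = h / 2;
  NumericVector Y((R_xlen_t)hp * rest);
  LogicalVector M((R_xlen_t)hp * rest);
  const double *x = REAL(X);
  double *y = REAL(Y);
  int *m = LOGICAL(M);
  for (int r = 0; r < rest; ++r) {
    const double *col = x + (std::size_t)r * h;
    double *yc = y + (std::size_t)r * hp;
    int *mc = m + (std::size_t)r * hp;
    for (int i = 0; i < hp; ++i) {
      const double a = col[2 * i], b = col[2 * i + 1];
      const bool top = a >= b;
      mc[i] = top;
      yc[i] = top ? a : b;
    }
  }
  return List::create(_["Y"] = Y, _["M"] = M);
}

// [[Rcpp::export(name = ".pool2x1BackwardC")]]
NumericVector pool2x1BackwardC(const NumericVector &dY,
                               const LogicalVector &M, int h, int rest) {
  const int hp = h / 2;
  NumericVector dX((R_xlen_t)h * rest);
  const double *dy = REAL(dY);
  const int *m = LOGICAL(M);
  double *dx = REAL(dX);
  for (int r = 0; r < rest; ++r) {
    const double *dyc = dy + (std::size_t)r * hp;
    const int *mc = m + (std::size_t)r * hp;
    double *dxc = dx + (std::size_t)r * h;
    for (int i = 0; i < hp; ++i) {
      if (mc[i]) dxc[2 * i] = dyc[i];
      else dxc[2 * i + 1] = dyc[i];
    }
  }
  return dX;
}
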