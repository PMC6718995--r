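#include <Rcpp.h>
using namespace Rcpp;

// Activation matrices are (N*H*W) x C with row index r = (n*H + y)*W + x.
// im2col column index is (c*k + ky)*k + kx, matching the conv weight layout.

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(const NumericMatrix& X, int N, int H, int W,
                          int k, int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H - k + 2 * pad) / stride + 1;
  const int Wo = (W - k + 2 * pad) / stride + 1;
  NumericMatrix out(N * Ho * Wo, k * k * C);
  const double* xp = X.begin();
  double* op = out.begin();
  const int xrows = X.nrow();
  const int orows = out.nrow();
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int col = (c * k + ky) * k + kx;
        double* ocol = op + (size_t)col * orows;
        const double* xcol = xp + (size_t)c * xrows;
        for (int n = 0; n < N; ++n) {
          for (int yo = 0; yo < Ho; ++yo) {
            const int y = yo * stride - pad + ky;
            const int rbase = (n * Ho + yo) * Wo;
            if (y < 0 || y >= H) continue;
            const int xbase = (n * H + y) * W;
            for (int xo = 0; xo < Wo; ++xo) {
              const int x = xo * stride - pad + kx;
              if (x < 0 || x >= W) continue;
              ocol[rbase + xo] = xcol[xbase + x];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_nhwc(const NumericMatrix& dCols, int N, int H, int W,
                          int C, int k, int stride, int pad) {
  const int Ho = (H - k + 2 * pad) / stride + 1;
  const int Wo = (W - k + 2 * pad) / stride + 1;
  NumericMatrix dX(N * H * W, C);
  const double* dp = dCols.begin();
  double* xp = dX.begin();
  const int drows = dCols.nrow();
  const int xrows = dX.nrow();
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int col = (c * k + ky) * k + kx;
        const double* dcol = dp + (size_t)col * drows;
        double* xcol = xp + (size_t)c * xrows;
        for (int n = 0; n < N; ++n) {
          for (int yo = 0; yo < Ho; ++yo) {
            const int y = yo * stride - pad + ky;
            if (y < 0 || y >= H) continue;
            const int rbase = (n * Ho + yo) * Wo;
            const int xbase = (n * H + y) * W;
            for (int xo = 0; xo < Wo; ++xo) {
              const int x = xo * stride - pad + kx;
              if (x < 0 || x >= W) continue;
              xcol[xbase + x] += dcol[rbase + xo];
            }
          }
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
List maxpool_nhwc(const NumericMatrix& X, int N, int H, int W,
                  int k, int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H - k + 2 * pad) / stride + 1;
  const int Wo = (W - k + 2 * pad) / stride + 1;
  NumericMatrix out(N * Ho * Wo, C);
  IntegerMatrix amax(N * Ho * Wo, C); // 1-based row index into X
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int yo = 0; yo < Ho; ++yo) {
        for (int xo = 0; xo < Wo; ++xo) {
          const int r = (n * Ho + yo) * Wo + xo;
          double best = R_NegInf;
          int besti = -1;
          for (int ky = 0; ky < k; ++ky) {
            const int y = yo * stride - pad + ky;
            if (y < 0 || y >= H) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int x = xo * stride - pad + kx;
              if (x < 0 || x >= W) continue;
              const int xi = (n * H + y) * W + x;
              const double v = X(xi, c);
              if (v > best) { best = v; besti = xi; }
            }
          }
          out(r, c) = best;
          amax(r, c) = besti + 1;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_nhwc(const NumericMatrix& dY,
                               const IntegerMatrix& amax, int nrow_x) {
  const int C = dY.ncol();
  NumericMatrix dX(nrow_x, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < dY.nrow(); ++r) {
      dX(amax(r, c) - 1, c) += dY(r, c);
    }
  }
  return dX;
}

// [[Rcpp::export]]
NumericVector colmeans_sq(const NumericMatrix& X) {
  const int n = X.nrow(), C = X.ncol();
  NumericVector out(C);
  const double* p = X.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0;
    const double* col = p + (size_t)c * n;
    for (int r = 0; r < n; ++r) s += col[r] * col[r];
    out[c] = s / n;
  }
  return out;
}

// y = X * a[col] + b[col]
// [[Rcpp::export]]
NumericMatrix colscale_shift(const NumericMatrix& X, const NumericVector& a,
                             const NumericVector& b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out(n, C);
  const double* p = X.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* col = p + (size_t)c * n;
    double* ocol = o + (size_t)c * n;
    for (int r = 0; r < n; ++r) ocol[r] = col[r] * ac + bc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix relu_fwd(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const double* p = X.begin();
  double* o = out.begin();
  const size_t len = (size_t)X.nrow() * X.ncol();
  for (size_t i = 0; i < len; ++i) o[i] = p[i] > 0 ? p[i] : 0;
  return out;
}

// gradient through ReLU given the forward output (a > 0 <=> pre-act > 0)
// [[Rcpp::export]]
NumericMatrix relu_bwd(const NumericMatrix& dA, const NumericMatrix& A) {
  NumericMatrix out(dA.nrow(), dA.ncol());
  const double* d = dA.begin();
  const double* a = A.begin();
  double* o = out.begin();
  const size_t len = (size_t)dA.nrow() * dA.ncol();
  for (size_t i = 0; i < len; ++i) o[i] = a[i] > 0 ? d[i] : 0;
  return out;
}

// Batch-norm backward, fused: returns dx, dgamma, dbeta without forming the
// usual large temporaries.
// [[Rcpp::export]]
List bn_bwd_fused(const NumericMatrix& dY, const NumericMatrix& Xhat,
                  const NumericVector& gamma, const NumericVector& istd) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  const double* dy = dY.begin();
  const double* xh = Xhat.begin();
  double* o = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy + (size_t)c * n;
    const double* xhc = xh + (size_t)c * n;
    double s1 = 0, s2 = 0, sg = 0;
    for (int r = 0; r < n; ++r) {
      const double d = dyc[r] * gamma[c];
      s1 += d;
      s2 += d * xhc[r];
      sg += dyc[r] * xhc[r];
    }
    dgamma[c] = sg;
    double sb = 0;
    for (int r = 0; r < n; ++r) sb += dyc[r];
    dbeta[c] = sb;
    const double m1 = s1 / n, m2 = s2 / n, sc = istd[c];
    double* oc = o + (size_t)c * n;
    for (int r = 0; r < n; ++r) {
      oc[r] = (dyc[r] * gamma[c] - m1 - xhc[r] * m2) * sc;
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
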