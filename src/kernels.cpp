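// Hot numerical kernels of the network: temporal convolution (via im2col +
// GEMM) and depthwise temporal convolution. Layouts match the R engine:
// activations (features, time, channels, batch), weights (Cout, Cin, K),
// all column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// The convolution is computed as K shifted GEMMs over a zero-padded
// contiguous layout: each (channel, trial) block of T time steps is laid
// out with K-1 zero columns after it (plus pl leading zeros), so the
// k-shifted column views never mix neighbouring blocks and the whole
// operand stays cache-resident across the K passes.

// Build the padded layout (Cin, TpCN + K - 1) from X (Cin, T, C, N).
static arma::mat pad_blocks(const double* X, int Cin, int T, long CN, int K,
                            int pl) {
  const int Tp = T + K - 1;
  arma::mat Xp(Cin, (long)Tp * CN + K - 1, arma::fill::zeros);
  for (long cn = 0; cn < CN; ++cn) {
    std::memcpy(Xp.colptr(pl + cn * Tp), X + cn * (long)Cin * T,
                sizeof(double) * (size_t)Cin * T);
  }
  return Xp;
}

// im2col gather for narrow kernels: S[(i,k), (t,cn)] = X[i, t+k-pl, cn].
static void im2col_t(const double* X, int Cin, int T, long CN, int K,
                     int pl, arma::mat& S) {
  const long ld = (long)Cin * K;
  double* Sb = S.memptr();
  for (long cn = 0; cn < CN; ++cn) {
    const double* Xcn = X + cn * (long)Cin * T;
    double* Scn = Sb + cn * (long)T * ld;
    for (int k = 0; k < K; ++k) {
      const int t0 = std::max(0, pl - k);
      const int t1 = std::min(T, T + pl - k);
      double* dst = Scn + (long)k * Cin;
      for (int t = 0; t < t0; ++t)
        std::fill(dst + (long)t * ld, dst + (long)t * ld + Cin, 0.0);
      for (int t = std::max(t1, t0); t < T; ++t)
        std::fill(dst + (long)t * ld, dst + (long)t * ld + Cin, 0.0);
      if (t1 <= t0) continue;
      const double* src = Xcn + (long)(t0 + k - pl) * Cin;
      double* d = dst + (long)t0 * ld;
      if (Cin == 1) {
        for (int t = t0; t < t1; ++t, d += ld, ++src) *d = *src;
      } else {
        for (int t = t0; t < t1; ++t, d += ld, src += Cin)
          std::memcpy(d, src, sizeof(double) * Cin);
      }
    }
  }
}

// Y (Cout, T, C, N) = conv(X, W) with left pad pl; W (Cout, Cin, K).
// Wide stacks (Cin*K large) use K shifted GEMMs over the cache-resident
// padded layout; narrow ones a single GEMM over the gathered im2col
// matrix (cheaper than K passes over the output when Cout > Cin).
static void conv_padded(const double* X, const double* W, const double* b,
                        int Cin, int T, long CN, int Cout, int K, int pl,
                        double* Yout) {
  if ((long)Cin * K <= 128) {
    arma::mat S((long)Cin * K, (long)T * CN);
    im2col_t(X, Cin, T, CN, K, pl, S);
    arma::mat Wm(const_cast<double*>(W), Cout, (long)Cin * K, false, true);
    arma::mat Ym(Yout, Cout, (long)T * CN, false, true);
    Ym = Wm * S;
  } else {
    const int Tp = T + K - 1;
    arma::mat Xp = pad_blocks(X, Cin, T, CN, K, pl);
    arma::mat Yp(Cout, (long)Tp * CN, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      const arma::mat Wk(const_cast<double*>(W) + (long)k * Cout * Cin,
                         Cout, Cin, false, true);
      Yp += Wk * Xp.cols(k, k + (long)Tp * CN - 1);
    }
    for (long cn = 0; cn < CN; ++cn) {
      std::memcpy(Yout + cn * (long)Cout * T, Yp.colptr(cn * Tp),
                  sizeof(double) * (size_t)Cout * T);
    }
  }
  if (b) {
    for (long j = 0; j < (long)T * CN; ++j)
      for (int o = 0; o < Cout; ++o) Yout[j * Cout + o] += b[o];
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_t_fwd(NumericVector X, NumericVector W,
                             NumericVector b, int pl) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int Cin = xd[0], T = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[0], K = wd[2];
  const long CN = (long)C * N;
  NumericVector out((R_xlen_t)Cout * T * CN);
  conv_padded(REAL(X), REAL(W), REAL(b), Cin, T, CN, Cout, K, pl, REAL(out));
  out.attr("dim") = IntegerVector::create(Cout, T, C, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_t_bwd(NumericVector dY, NumericVector X, NumericVector W,
                    int pl, bool need_dx) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int Cin = xd[0], T = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[0], K = wd[2];
  const long CN = (long)C * N;
  const int Tp = T + K - 1;
  arma::mat dYm(const_cast<double*>(REAL(dY)), Cout, (long)T * CN,
                false, true);

  NumericVector dW((R_xlen_t)Cout * Cin * K);
  if ((long)Cin * K <= 128) {
    arma::mat S((long)Cin * K, (long)T * CN);
    im2col_t(REAL(X), Cin, T, CN, K, pl, S);
    arma::mat dWm(REAL(dW), Cout, (long)Cin * K, false, true);
    dWm = dYm * S.t();
  } else {
    // dW_k = dY * shift_k(X)^T over the padded layout: output column j
    // pairs with padded-X column (j + k), exactly as in the forward
    // pass; the zero pad columns of dYp contribute nothing.
    arma::mat Xp = pad_blocks(REAL(X), Cin, T, CN, K, pl);
    arma::mat dYp = pad_blocks(REAL(dY), Cout, T, CN, K, 0);
    for (int k = 0; k < K; ++k) {
      arma::mat dWk(REAL(dW) + (long)k * Cout * Cin, Cout, Cin, false, true);
      dWk = dYp.cols(0, (long)Tp * CN - 1) *
        Xp.cols(k, k + (long)Tp * CN - 1).t();
    }
  }
  dW.attr("dim") = IntegerVector::create(Cout, Cin, K);

  NumericVector db(Cout);
  {
    arma::vec dbv(REAL(db), Cout, false, true);
    dbv = arma::sum(dYm, 1);
  }

  List out = List::create(Named("dW") = dW, Named("db") = db,
                          Named("dX") = R_NilValue);
  if (need_dx) {
    // input gradient = correlation of dY with the in/out-transposed,
    // time-flipped kernel at complementary padding
    NumericVector Wf((R_xlen_t)Cin * Cout * K);
    const double* w = REAL(W);
    double* wf = REAL(Wf);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < Cin; ++i)
        for (int o = 0; o < Cout; ++o)
          wf[i + (long)Cin * o + (long)Cin * Cout * k] =
            w[o + (long)Cout * i + (long)Cout * Cin * (K - 1 - k)];
    NumericVector dX((R_xlen_t)Cin * T * CN);
    conv_padded(REAL(dY), wf, nullptr, Cout, T, CN, Cin, K, K - 1 - pl,
                REAL(dX));
    dX.attr("dim") = IntegerVector::create(Cin, T, C, N);
    out["dX"] = dX;
  }
  return out;
}

// Spatial depthwise convolution over the channel axis ('valid', collapses
// C to 1 with depth multiplier D). X (F, T, C, N); W (C, F, D);
// Y ((f-1)*D+d, t, 1, n) = sum_c W[c,f,d] X[f,t,c,n].
// [[Rcpp::export]]
NumericVector cpp_dws_fwd(NumericVector X, NumericVector W) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int F = xd[0], T = xd[1], C = xd[2], N = xd[3], D = wd[2];
  NumericVector out((R_xlen_t)F * D * T * N);
  double* y = REAL(out);
  const double* x = REAL(X);
  const double* w = REAL(W);
  std::fill(y, y + out.size(), 0.0);
  for (long n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + ((long)n * C + c) * (long)F * T;
      const double* wc = w + c;                 // stride C over (f, d)
      double* yn = y + (long)n * F * D * T;
      for (int t = 0; t < T; ++t) {
        const double* xt = xc + (long)t * F;
        double* yt = yn + (long)t * F * D;
        for (int f = 0; f < F; ++f)
          for (int d = 0; d < D; ++d)
            yt[f * D + d] += wc[(long)(d * F + f) * C] * xt[f];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(F * D, T, 1, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dws_bwd(NumericVector dY, NumericVector X, NumericVector W) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int F = xd[0], T = xd[1], C = xd[2], N = xd[3], D = wd[2];
  NumericVector dX(X.size()), dW(W.size());
  double* dx = REAL(dX);
  double* dw = REAL(dW);
  const double* dy = REAL(dY);
  const double* x = REAL(X);
  const double* w = REAL(W);
  std::fill(dx, dx + dX.size(), 0.0);
  std::fill(dw, dw + dW.size(), 0.0);
  for (long n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + ((long)n * C + c) * (long)F * T;
      double* dxc = dx + ((long)n * C + c) * (long)F * T;
      const double* wc = w + c;
      double* dwc = dw + c;
      const double* dyn = dy + (long)n * F * D * T;
      for (int t = 0; t < T; ++t) {
        const double* xt = xc + (long)t * F;
        double* dxt = dxc + (long)t * F;
        const double* dyt = dyn + (long)t * F * D;
        for (int f = 0; f < F; ++f) {
          double acc = 0.0;
          for (int d = 0; d < D; ++d) {
            const long wi = (long)(d * F + f) * C;
            acc += wc[wi] * dyt[f * D + d];
            dwc[wi] += xt[f] * dyt[f * D + d];
          }
          dxt[f] += acc;
        }
      }
    }
  }
  dX.attr("dim") = X.attr("dim");
  dW.attr("dim") = W.attr("dim");
  return List::create(Named("dX") = dX, Named("dW") = dW);
}

// Mean over the channel axis: X (F, T, C, N) -> (F, T, 1, N).
// [[Rcpp::export]]
NumericVector cpp_chmean_fwd(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int F = xd[0], T = xd[1], C = xd[2], N = xd[3];
  NumericVector out((R_xlen_t)F * T * N);
  double* y = REAL(out);
  const double* x = REAL(X);
  std::fill(y, y + out.size(), 0.0);
  const long FT = (long)F * T;
  for (long n = 0; n < N; ++n) {
    double* yn = y + n * FT;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (n * C + (long)c) * FT;
      for (long i = 0; i < FT; ++i) yn[i] += xc[i];
    }
    for (long i = 0; i < FT; ++i) yn[i] /= C;
  }
  out.attr("dim") = IntegerVector::create(F, T, 1, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chmean_bwd(NumericVector dY, int C) {
  IntegerVector yd = dY.attr("dim");
  const int F = yd[0], T = yd[1], N = yd[3];
  const long FT = (long)F * T;
  NumericVector dX((R_xlen_t)F * T * C * N);
  double* dx = REAL(dX);
  const double* dy = REAL(dY);
  for (long n = 0; n < N; ++n) {
    const double* dn = dy + n * FT;
    for (int c = 0; c < C; ++c) {
      double* dc = dx + (n * (long)C + c) * FT;
      for (long i = 0; i < FT; ++i) dc[i] = dn[i] / C;
    }
  }
  dX.attr("dim") = IntegerVector::create(F, T, C, N);
  return dX;
}

// Batch normalisation over the leading (feature) axis, fused statistics.
// Returns Y plus the per-feature mean and inverse std used, and updates
// the running statistics in place when use_batch is true.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector X, NumericVector g, NumericVector b,
                NumericVector rm, NumericVector rv, double momentum,
                double eps, bool use_batch) {
  IntegerVector xd = X.attr("dim");
  const int F = xd[0];
  const long n = X.size() / F;
  const double* x = REAL(X);
  NumericVector mu(F), istd(F);
  NumericVector rm2 = clone(rm), rv2 = clone(rv);
  if (use_batch) {
    std::vector<double> s1(F, 0.0), s2(F, 0.0);
    for (long j = 0; j < n; ++j) {
      const double* xj = x + j * F;
      for (int f = 0; f < F; ++f) { s1[f] += xj[f]; s2[f] += xj[f] * xj[f]; }
    }
    for (int f = 0; f < F; ++f) {
      mu[f] = s1[f] / n;
      const double v = s2[f] / n - mu[f] * mu[f];
      istd[f] = 1.0 / std::sqrt(v + eps);
      rm2[f] = momentum * rm2[f] + (1 - momentum) * mu[f];
      rv2[f] = momentum * rv2[f] + (1 - momentum) * v;
    }
  } else {
    for (int f = 0; f < F; ++f) {
      mu[f] = rm[f];
      istd[f] = 1.0 / std::sqrt(rv[f] + eps);
    }
  }
  NumericVector Y(X.size());
  double* y = REAL(Y);
  const double* gp = REAL(g);
  const double* bp = REAL(b);
  for (long j = 0; j < n; ++j) {
    const double* xj = x + j * F;
    double* yj = y + j * F;
    for (int f = 0; f < F; ++f)
      yj[f] = gp[f] * (xj[f] - mu[f]) * istd[f] + bp[f];
  }
  Y.attr("dim") = X.attr("dim");
  return List::create(Named("Y") = Y, Named("mu") = mu, Named("istd") = istd,
                      Named("rm") = rm2, Named("rv") = rv2);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dY, NumericVector X, NumericVector g,
                NumericVector mu, NumericVector istd, bool use_batch) {
  IntegerVector xd = X.attr("dim");
  const int F = xd[0];
  const long n = X.size() / F;
  const double* x = REAL(X);
  const double* dy = REAL(dY);
  const double* gp = REAL(g);
  NumericVector dg(F), db(F);
  std::vector<double> sdxh(F, 0.0), sdxx(F, 0.0);
  for (long j = 0; j < n; ++j) {
    const double* xj = x + j * F;
    const double* dj = dy + j * F;
    for (int f = 0; f < F; ++f) {
      const double xh = (xj[f] - mu[f]) * istd[f];
      dg[f] += dj[f] * xh;
      db[f] += dj[f];
      sdxh[f] += dj[f] * gp[f];            // sum of dxhat
      sdxx[f] += dj[f] * gp[f] * xh;       // sum of dxhat * xhat
    }
  }
  NumericVector dX(X.size());
  double* dx = REAL(dX);
  if (use_batch) {
    for (long j = 0; j < n; ++j) {
      const double* xj = x + j * F;
      const double* dj = dy + j * F;
      double* dxj = dx + j * F;
      for (int f = 0; f < F; ++f) {
        const double xh = (xj[f] - mu[f]) * istd[f];
        dxj[f] = istd[f] * (dj[f] * gp[f] - sdxh[f] / n - xh * sdxx[f] / n);
      }
    }
  } else {
    for (long j = 0; j < n; ++j) {
      const double* dj = dy + j * F;
      double* dxj = dx + j * F;
      for (int f = 0; f < F; ++f) dxj[f] = dj[f] * gp[f] * istd[f];
    }
  }
  dX.attr("dim") = X.attr("dim");
  return List::create(Named("dX") = dX, Named("dg") = dg, Named("db") = db);
}

// ELU (alpha = 1) and its gradient expressed through the output.
// [[Rcpp::export]]
NumericVector cpp_elu_fwd(NumericVector X) {
  NumericVector Y(X.size());
  const double* x = REAL(X);
  double* y = REAL(Y);
  const long n = X.size();
  for (long i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_bwd(NumericVector dY, NumericVector Y) {
  NumericVector dX(Y.size());
  const double* dy = REAL(dY);
  const double* y = REAL(Y);
  double* dx = REAL(dX);
  const long n = Y.size();
  for (long i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : dy[i] * (y[i] + 1);
  dX.attr("dim") = Y.attr("dim");
  return dX;
}

// Depthwise temporal convolution: Z[f,t,n] = sum_k Wd[f,k] X[f,t+k-pl,n].
// X dims (F, T, 1, N); Wd (F, K).
// [[Rcpp::export]]
NumericVector cpp_dwt_fwd(NumericVector X, NumericMatrix Wd, int pl) {
  IntegerVector xd = X.attr("dim");
  const int F = xd[0], T = xd[1], N = xd[3];
  const int K = Wd.ncol();
  NumericVector out((R_xlen_t)F * T * N);
  double* z = REAL(out);
  const double* x = REAL(X);
  const double* w = REAL(Wd);
  std::fill(z, z + (long)F * T * N, 0.0);
  for (long n = 0; n < N; ++n) {
    const double* xn = x + n * (long)F * T;
    double* zn = z + n * (long)F * T;
    for (int t = 0; t < T; ++t) {
      double* zt = zn + (long)t * F;
      for (int k = 0; k < K; ++k) {
        const int src = t + k - pl;
        if (src < 0 || src >= T) continue;
        const double* xs = xn + (long)src * F;
        const double* wk = w + (long)k * F;
        for (int f = 0; f < F; ++f) zt[f] += wk[f] * xs[f];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(F, T, 1, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwt_bwd(NumericVector dZ, NumericVector X, NumericMatrix Wd,
                 int pl) {
  IntegerVector xd = X.attr("dim");
  const int F = xd[0], T = xd[1], N = xd[3];
  const int K = Wd.ncol();
  NumericVector dX((R_xlen_t)F * T * N);
  NumericMatrix dWd(F, K);
  double* dx = REAL(dX);
  double* dw = REAL(dWd);
  const double* dz = REAL(dZ);
  const double* x = REAL(X);
  const double* w = REAL(Wd);
  std::fill(dx, dx + (long)F * T * N, 0.0);
  for (long n = 0; n < N; ++n) {
    const double* xn = x + n * (long)F * T;
    const double* dzn = dz + n * (long)F * T;
    double* dxn = dx + n * (long)F * T;
    for (int t = 0; t < T; ++t) {
      const double* dzt = dzn + (long)t * F;
      for (int k = 0; k < K; ++k) {
        const int src = t + k - pl;
        if (src < 0 || src >= T) continue;
        const double* xs = xn + (long)src * F;
        double* dxs = dxn + (long)src * F;
        const double* wk = w + (long)k * F;
        double* dwk = dw + (long)k * F;
        for (int f = 0; f < F; ++f) {
          dxs[f] += wk[f] * dzt[f];
          dwk[f] += xs[f] * dzt[f];
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(F, T, 1, N);
  return List::create(Named("dX") = dX, Named("dWd") = dWd);
}
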