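// Dense compute kernels for the segmentation networks.
//
// Tensor layout is the R array convention (H, W, C, N), column-major, so the
// element (h, w, c, n) [0-based] lives at h + H*(w + W*(c + C*n)).  Convolution
// is stride-1 with symmetric zero padding.  im2col is built transposed,
// (H*W*N) x (K*K*C), so each (kh, kw, c) slot is one contiguous column copied
// with shifted sequential reads from x; the convolution is then a single
// GEMM against the (K*K*C) x Cout weight matrix with no transposition.
// GEMMs run in single precision: parameters and activations cross the R
// boundary as doubles, but convolution arithmetic uses float, which is the
// customary precision for CNN training and roughly doubles throughput.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector new_arr4(int H, int W, int C, int N) {
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

static IntegerVector new_iarr4(int H, int W, int C, int N) {
  IntegerVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// colsT is (HWN x KKC): column r = kh + K*kw + K*K*c holds, for every output
// position (h, w, n), the input value at (h + kh - pad, w + kw - pad, c, n).
static arma::fmat im2colT(const double* x, int H, int W, int C, int N,
                         int K, int pad) {
  const long long HW = (long long)H * W;
  arma::fmat colsT(HW * N, (long long)K * K * C);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        float* col = colsT.colptr(kh + (long long)K * kw + (long long)K * K * c);
        const int dh = kh - pad, dw = kw - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + HW * (c + (long long)C * n);
          float* oc = col + HW * n;
          for (int w = 0; w < w0; ++w)
            std::fill(oc + (long long)H * w, oc + (long long)H * w + H, 0.0f);
          for (int w = w0; w < w1; ++w) {
            const double* src = xc + (long long)H * (w + dw) + dh;
            float* dst = oc + (long long)H * w;
            for (int h = 0; h < h0; ++h) dst[h] = 0.0f;
            for (int h = h0; h < h1; ++h) dst[h] = (float)src[h];
            for (int h = h1; h < H; ++h) dst[h] = 0.0f;
          }
          for (int w = w1; w < W; ++w)
            std::fill(oc + (long long)H * w, oc + (long long)H * w + H, 0.0f);
        }
      }
  return colsT;
}

static void col2imT_acc(const arma::fmat& dcolsT, double* dx,
                        int H, int W, int C, int N, int K, int pad) {
  const long long HW = (long long)H * W;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const float* col =
          dcolsT.colptr(kh + (long long)K * kw + (long long)K * K * c);
        const int dh = kh - pad, dw = kw - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int n = 0; n < N; ++n) {
          double* xc = dx + HW * (c + (long long)C * n);
          const float* oc = col + HW * n;
          for (int w = w0; w < w1; ++w) {
            double* dst = xc + (long long)H * (w + dw) + dh;
            const float* src = oc + (long long)H * w;
            for (int h = h0; h < h1; ++h) dst[h] += (double)src[h];
          }
        }
      }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// (H, W, Cout, N) <-> (HWN x Cout) matrix with rows ordered (h, w, n)
static void mat_to_arr(const arma::fmat& Y, double* out, int H, int W,
                       int Cout, int N, const double* bias) {
  const long long HW = (long long)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* op = out + HW * (co + (long long)Cout * n);
      const float* yp = Y.colptr(co) + HW * n;
      const double bb = bias ? bias[co] : 0.0;
      for (long long i = 0; i < HW; ++i) op[i] = (double)yp[i] + bb;
    }
}

static arma::fmat arr_to_mat(const double* dy, int H, int W, int Cout, int N) {
  const long long HW = (long long)H * W;
  arma::fmat M(HW * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dp = dy + HW * (co + (long long)Cout * n);
      float* mp = M.colptr(co) + HW * n;
      for (long long i = 0; i < HW; ++i) mp[i] = (float)dp[i];
    }
  return M;
}

static arma::fmat to_f(const arma::mat& m) { return arma::conv_to<arma::fmat>::from(m); }

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, const arma::mat& wmat,
                            NumericVector bias, int K, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = wmat.n_cols;
  if ((int)wmat.n_rows != K * K * C)
    stop("weight matrix rows do not match K*K*C");
  arma::fmat Y = im2colT(x.begin(), H, W, C, N, K, pad) * to_f(wmat);  // (HWN x Cout)
  NumericVector out = new_arr4(H, W, Cout, N);
  mat_to_arr(Y, out.begin(), H, W, Cout, N, bias.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, const arma::mat& wmat,
                   NumericVector dy, int K, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = wmat.n_cols;
  arma::fmat dymat = arr_to_mat(dy.begin(), H, W, Cout, N);
  arma::fmat colsT = im2colT(x.begin(), H, W, C, N, K, pad);
  arma::mat dW = arma::conv_to<arma::mat>::from(colsT.t() * dymat);  // (KKC x Cout)
  arma::frowvec dbf = arma::sum(dymat, 0);
  arma::rowvec db = arma::conv_to<arma::rowvec>::from(dbf);
  arma::fmat dcolsT = dymat * to_f(wmat).t();     // (HWN x KKC)
  NumericVector dx = new_arr4(H, W, C, N);
  col2imT_acc(dcolsT, dx.begin(), H, W, C, N, K, pad);
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling).
// wmat is (Cin x 4*Cout); column index co + Cout*(a + 2*b) holds the weight
// feeding output offset (a, b) within each 2x2 block.
// [[Rcpp::export]]
NumericVector cpp_convT2_fw(NumericVector x, const arma::mat& wmat,
                            NumericVector bias) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = wmat.n_cols / 4;
  if ((int)wmat.n_rows != C) stop("weight rows do not match Cin");
  const long long HW = (long long)H * W;
  arma::fmat Xm = arr_to_mat(x.begin(), H, W, C, N);
  arma::fmat Y = Xm * to_f(wmat);  // (HWN x 4Cout)
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out = new_arr4(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* op = out.begin() + (long long)H2 * W2 * (co + (long long)Cout * n);
      const double bb = bias[co];
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const float* yp = Y.colptr(co + Cout * (a + 2 * b)) + HW * n;
          for (int w = 0; w < W; ++w) {
            double* dst = op + (long long)H2 * (2 * w + b) + a;
            const float* src = yp + (long long)H * w;
            for (int h = 0; h < H; ++h) dst[2 * h] = (double)src[h] + bb;
          }
        }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_convT2_bw(NumericVector x, const arma::mat& wmat, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = wmat.n_cols / 4;
  const int H2 = 2 * H, W2 = 2 * W;
  const long long HW = (long long)H * W;
  arma::fmat dYm(HW * N, 4 * Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dp =
        dy.begin() + (long long)H2 * W2 * (co + (long long)Cout * n);
      double acc = 0.0;
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          float* yp = dYm.colptr(co + Cout * (a + 2 * b)) + HW * n;
          for (int w = 0; w < W; ++w) {
            const double* src = dp + (long long)H2 * (2 * w + b) + a;
            float* dst = yp + (long long)H * w;
            for (int h = 0; h < H; ++h) { dst[h] = (float)src[2 * h]; acc += src[2 * h]; }
          }
        }
      db[co] += acc;
    }
  arma::fmat Xm = arr_to_mat(x.begin(), H, W, C, N);
  arma::mat dW = arma::conv_to<arma::mat>::from(Xm.t() * dYm);  // (Cin x 4Cout)
  arma::fmat dXm = dYm * to_f(wmat).t();                        // (HWN x Cin)
  NumericVector dx = new_arr4(H, W, C, N);
  mat_to_arr(dXm, dx.begin(), H, W, C, N, nullptr);
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = db);
}

// 2x2 max pooling, stride 2; ties resolved to the first position in the
// order (0,0), (1,0), (0,1), (1,1) within the block (column-major).
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = new_arr4(Ho, Wo, C, N);
  IntegerVector idx = new_iarr4(Ho, Wo, C, N);
  const long long HW = (long long)H * W, HWo = (long long)Ho * Wo;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* xp = x.begin() + HW * cn;
    double* yp = y.begin() + HWo * cn;
    int* ip = idx.begin() + HWo * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = -HUGE_VAL; int bi = 0, k = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const double v = xp[(2 * h + a) + (long long)H * (2 * w + b)];
            if (v > best) { best = v; bi = k; }
            ++k;
          }
        yp[h + (long long)Ho * w] = best;
        ip[h + (long long)Ho * w] = bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx,
                              int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = new_arr4(H, W, C, N);
  const long long HW = (long long)H * W, HWo = (long long)Ho * Wo;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* dp = dy.begin() + HWo * cn;
    const int* ip = idx.begin() + HWo * cn;
    double* xp = dx.begin() + HW * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int k = ip[h + (long long)Ho * w];
        const int a = k % 2, b = k / 2;
        xp[(2 * h + a) + (long long)H * (2 * w + b)] += dp[h + (long long)Ho * w];
      }
  }
  return dx;
}

// ---- channel-wise helpers for batch normalization and ReLU ----------------

// [[Rcpp::export]]
NumericVector cpp_ch_sum(NumericVector x) {
  IntegerVector d = dims4(x);
  const long long HW = (long long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (long long)C * n);
      double acc = 0.0;
      for (long long i = 0; i < HW; ++i) acc += xp[i];
      out[c] += acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ch_dot(NumericVector x, NumericVector y) {
  IntegerVector d = dims4(x);
  const long long HW = (long long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long long off = HW * (c + (long long)C * n);
      const double* xp = x.begin() + off;
      const double* yp = y.begin() + off;
      double acc = 0.0;
      for (long long i = 0; i < HW; ++i) acc += xp[i] * yp[i];
      out[c] += acc;
    }
  return out;
}

// y[h,w,c,n] = x[h,w,c,n] * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_ch_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector d = dims4(x);
  const long long HW = (long long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out = new_arr4(d[0], d[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long long off = HW * (c + (long long)C * n);
      const double* xp = x.begin() + off;
      double* op = out.begin() + off;
      const double aa = a[c], bb = b[c];
      for (long long i = 0; i < HW; ++i) op[i] = xp[i] * aa + bb;
    }
  return out;
}

// dx = (ivar[c]/M) * (M*dxhat - s1[c] - xhat*s2[c])
// [[Rcpp::export]]
NumericVector cpp_bn_bw(NumericVector dxhat, NumericVector xhat,
                        NumericVector s1, NumericVector s2,
                        NumericVector ivar, double M) {
  IntegerVector d = dims4(dxhat);
  const long long HW = (long long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out = new_arr4(d[0], d[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long long off = HW * (c + (long long)C * n);
      const double* dp = dxhat.begin() + off;
      const double* hp = xhat.begin() + off;
      double* op = out.begin() + off;
      const double k = ivar[c] / M, a = s1[c], b = s2[c];
      for (long long i = 0; i < HW; ++i)
        op[i] = k * (M * dp[i] - a - hp[i] * b);
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector out(clone(x));
  double* p = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector gy, NumericVector y) {
  NumericVector out(clone(gy));
  double* p = out.begin();
  const double* yp = y.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] <= 0) p[i] = 0;
  return out;
}
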