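// Strided 2-D (transposed) convolution kernels for the phase-encoder network.
// Tensors use the R array layout (H, W, C, N), column-major. im2col rows are
// ordered (dh, dw, c) so that a weight array (kh, kw, Cin, Cout) flattens to a
// conformable (kh*kw*Cin) x Cout matrix without any permutation. The im2col
// matrix spans the whole batch, so each pass is a single BLAS gemm; the
// forward pass can hand its column matrix back to the caller so the backward
// pass skips re-materializing it.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_slab(const double* x, int H, int W, int C,
                        int kh, int kw, int sh, int sw, int ph, int pw,
                        int Ho, int Wo, double* colptr, int nrows) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * sw - pw + dw;
          if (w < 0 || w >= W) continue;
          const double* xcol = xc + (size_t)w * H;
          double* crow = colptr + r + (size_t)nrows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * sh - ph + dh;
            if (h < 0 || h >= H) continue;
            crow[(size_t)nrows * ho] = xcol[h];
          }
        }
      }
    }
  }
}

static void col2im_slab(const double* colptr, int nrows, int H, int W, int C,
                        int kh, int kw, int sh, int sw, int ph, int pw,
                        int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * sw - pw + dw;
          if (w < 0 || w >= W) continue;
          double* xcol = xc + (size_t)w * H;
          const double* crow = colptr + r + (size_t)nrows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * sh - ph + dh;
            if (h < 0 || h >= H) continue;
            xcol[h] += crow[(size_t)nrows * ho];
          }
        }
      }
    }
  }
}

static Rcpp::IntegerVector dims4(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-D array (H, W, C, N)");
  return d;
}

static Rcpp::NumericVector array4(int a, int b, int c, int d) {
  Rcpp::NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

// inference-mode BatchNorm folded to a single per-channel multiply-add
// [[Rcpp::export]]
Rcpp::NumericVector bn_eval_cpp(Rcpp::NumericVector x, Rcpp::NumericVector a,
                                Rcpp::NumericVector b) {
  Rcpp::IntegerVector d = dims4(x);
  const int hw = d[0] * d[1], C = d[2], N = d[3];
  if (a.size() != C || b.size() != C) Rcpp::stop("scale/shift length mismatch");
  Rcpp::NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const size_t off = ((size_t)n * C + c) * hw;
      for (int j = 0; j < hw; ++j) yp[off + j] = xp[off + j] * ac + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector bias,
                          int sh, int sw, int ph, int pw,
                          Rcpp::Nullable<Rcpp::NumericMatrix> cols_buf =
                            R_NilValue) {
  Rcpp::IntegerVector dx = dims4(x), dw_ = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cin = dw_[2], Cout = dw_[3];
  if (Cin != C) Rcpp::stop("input channels do not match weights");
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int K = kh * kw * Cin;

  // reuse the caller's column buffer when its shape matches; saves one
  // large allocation + GC churn per layer call during training
  Rcpp::NumericMatrix cols;
  if (cols_buf.isNotNull()) {
    Rcpp::NumericMatrix cb(cols_buf);
    if (cb.nrow() == K && cb.ncol() == (R_xlen_t)Ho * Wo * N) cols = cb;
    else cols = Rcpp::NumericMatrix(K, Ho * Wo * N);
  } else {
    cols = Rcpp::NumericMatrix(K, Ho * Wo * N);
  }
  std::fill(cols.begin(), cols.end(), 0.0);
  for (int n = 0; n < N; ++n)
    im2col_slab(x.begin() + (size_t)n * H * W * C, H, W, C,
                kh, kw, sh, sw, ph, pw, Ho, Wo,
                cols.begin() + (size_t)n * K * Ho * Wo, K);
  const mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const mat Cm(cols.begin(), K, (size_t)Ho * Wo * N, false, true);
  mat Y = Wm.t() * Cm;  // Cout x (Ho*Wo*N)

  Rcpp::NumericVector y = array4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double b = bias[co];
      const size_t off = (size_t)n * Ho * Wo;
      for (int j = 0; j < Ho * Wo; ++j)
        yp[(size_t)co * Ho * Wo + j] = Y(co, off + j) + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(Rcpp::NumericMatrix cols, Rcpp::NumericVector w,
                          Rcpp::NumericVector gy, Rcpp::IntegerVector xdim,
                          int sh, int sw, int ph, int pw) {
  Rcpp::IntegerVector dw_ = dims4(w), dg = dims4(gy);
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = dw_[0], kw = dw_[1], Cin = dw_[2], Cout = dw_[3];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) Rcpp::stop("gradient dims do not match");
  const int K = kh * kw * Cin;
  if (cols.nrow() != K || cols.ncol() != (R_xlen_t)Ho * Wo * N)
    Rcpp::stop("cached column matrix does not match this layer");

  // gather gy into (Cout) x (Ho*Wo*N) and per-channel bias sums
  mat G(Cout, (size_t)Ho * Wo * N);
  Rcpp::NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* gp = gy.begin() + (size_t)n * Ho * Wo * Cout;
    const size_t off = (size_t)n * Ho * Wo;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int j = 0; j < Ho * Wo; ++j) {
        const double v = gp[(size_t)co * Ho * Wo + j];
        G(co, off + j) = v;
        s += v;
      }
      gb[co] += s;
    }
  }
  const mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const mat Cm(cols.begin(), K, (size_t)Ho * Wo * N, false, true);
  Rcpp::NumericVector gw = array4(kh, kw, Cin, Cout);
  mat GWm(gw.begin(), K, Cout, false, true);
  GWm = Cm * G.t();
  mat Gcols = Wm * G;  // K x (Ho*Wo*N)

  Rcpp::NumericVector gx = array4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    col2im_slab(Gcols.memptr() + (size_t)n * K * Ho * Wo, K, H, W, C,
                kh, kw, sh, sw, ph, pw, Ho, Wo,
                gx.begin() + (size_t)n * H * W * C);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Transposed convolution: maps (H, W, Cin) -> (Ho, Wo, Cout) where the
// associated reference convolution maps (Ho, Wo, Cout) -> (H, W, Cin).
// Weights: (kh, kw, Cout, Cin).
// [[Rcpp::export]]
Rcpp::NumericVector tconv2d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                    Rcpp::NumericVector bias,
                                    int sh, int sw, int ph, int pw,
                                    int Ho, int Wo) {
  Rcpp::IntegerVector dx = dims4(x), dw_ = dims4(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[2];
  if (dw_[3] != Cin) Rcpp::stop("input channels do not match weights");
  if ((Ho + 2 * ph - kh) / sh + 1 != H || (Wo + 2 * pw - kw) / sw + 1 != W)
    Rcpp::stop("requested output size inconsistent with kernel/stride/pad");
  const int K = kh * kw * Cout;

  // gather x into (Cin) x (H*W*N)
  mat X(Cin, (size_t)H * W * N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * Cin;
    const size_t off = (size_t)n * H * W;
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < H * W; ++j) X(c, off + j) = xp[(size_t)c * H * W + j];
  }
  const mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  mat cols = Wm * X;  // K x (H*W*N)

  Rcpp::NumericVector y = array4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    col2im_slab(cols.memptr() + (size_t)n * K * H * W, K, Ho, Wo, Cout,
                kh, kw, sh, sw, ph, pw, H, W, yp);
    for (int co = 0; co < Cout; ++co) {
      const double b = bias[co];
      for (int j = 0; j < Ho * Wo; ++j) yp[(size_t)co * Ho * Wo + j] += b;
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List tconv2d_bwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                           Rcpp::NumericVector gy,
                           int sh, int sw, int ph, int pw) {
  Rcpp::IntegerVector dx = dims4(x), dw_ = dims4(w), dg = dims4(gy);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[2];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) Rcpp::stop("gradient dims do not match");
  const int K = kh * kw * Cout;

  mat cols((size_t)K, (size_t)H * W * N, fill::zeros);
  Rcpp::NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* gp = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int j = 0; j < Ho * Wo; ++j) s += gp[(size_t)co * Ho * Wo + j];
      gb[co] += s;
    }
    im2col_slab(gp, Ho, Wo, Cout, kh, kw, sh, sw, ph, pw, H, W,
                cols.memptr() + (size_t)n * K * H * W, K);
  }
  mat X(Cin, (size_t)H * W * N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * Cin;
    const size_t off = (size_t)n * H * W;
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < H * W; ++j) X(c, off + j) = xp[(size_t)c * H * W + j];
  }
  const mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  Rcpp::NumericVector gw = array4(kh, kw, Cout, Cin);
  mat GWm(gw.begin(), K, Cin, false, true);
  GWm = cols * X.t();
  mat GX = Wm.t() * cols;  // Cin x (H*W*N)

  Rcpp::NumericVector gx = array4(H, W, Cin, N);
  for (int n = 0; n < N; ++n) {
    double* gxp = gx.begin() + (size_t)n * H * W * Cin;
    const size_t off = (size_t)n * H * W;
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < H * W; ++j) gxp[(size_t)c * H * W + j] = GX(c, off + j);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
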