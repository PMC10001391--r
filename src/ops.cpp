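// Low-level array kernels for the network layers.
//
// All feature maps are R double arrays with dim (H, W, C, N), column-major,
// so index(h, w, c, n) = h + H*(w + W*(c + C*n)).  Dense convolution weights
// are (kh, kw, Cin, Cout); depthwise weights are (kh, kw, C).  Convolutions
// use im2col + BLAS gemm; the backward passes are exact adjoints of the
// forward linear maps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix M (Ho*Wo x kh*kw*Cin) for sample n.
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& M) {
  const double* xs = x + (size_t)H * W * C * n;
  for (int c = 0; c < C; ++c) {
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        int q = ik + kh * (jk + kw * c);
        double* col = M.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + jk;
          bool win = (wi >= 0 && wi < W);
          const double* xcol = xs + (size_t)H * (wi + W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ik;
            col[ho + Ho * wo] =
              (win && hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col: dM (Ho*Wo x K) back into dx sample n.
static void col2im(const arma::mat& dM, double* dx, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  double* xs = dx + (size_t)H * W * C * n;
  for (int c = 0; c < C; ++c) {
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        int q = ik + kh * (jk + kw * c);
        const double* col = dM.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + jk;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xs + (size_t)H * (wi + W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ik;
            if (hi >= 0 && hi < H) xcol[hi] += col[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int K = kh * kw * C;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat M(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout,
                false, true);
    Y = M * Wm;
    if (b.size() == (R_xlen_t)Cout)
      for (int oc = 0; oc < Cout; ++oc) Y.col(oc) += b[oc];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int K = kh * kw * C;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat M(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat dY(dy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout,
                 false, true);
    dWm += M.t() * dY;
    arma::mat dM = dY * Wm.t();
    col2im(dM, dx.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo);
    if (has_bias)
      for (int oc = 0; oc < Cout; ++oc) db[oc] += arma::accu(dY.col(oc));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w,
                               NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  bool has_bias = b.size() == (R_xlen_t)C;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double bias = has_bias ? b[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias;
          for (int jk = 0; jk < kw; ++jk) {
            int wi = wo * stride - pad + jk;
            if (wi < 0 || wi >= W) continue;
            for (int ik = 0; ik < kh; ++ik) {
              int hi = ho * stride - pad + ik;
              if (hi < 0 || hi >= H) continue;
              acc += xs[hi + H * wi] * wc[ik + kh * jk];
            }
          }
          ys[ho + Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * C);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? C : 0);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dys = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dys[ho + Ho * wo];
          if (g == 0.0) continue;
          for (int jk = 0; jk < kw; ++jk) {
            int wi = wo * stride - pad + jk;
            if (wi < 0 || wi >= W) continue;
            for (int ik = 0; ik < kh; ++ik) {
              int hi = ho * stride - pad + ik;
              if (hi < 0 || hi >= H) continue;
              dwc[ik + kh * jk] += xs[hi + H * wi] * g;
              dxs[hi + H * wi] += wc[ik + kh * jk] * g;
            }
          }
        }
      }
      if (has_bias) {
        double s = 0.0;
        for (int i = 0; i < Ho * Wo; ++i) s += dys[i];
        db[c] += s;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* is = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int jk = 0; jk < k; ++jk) {
            int wi = wo * stride - pad + jk;
            if (wi < 0 || wi >= W) continue;
            for (int ik = 0; ik < k; ++ik) {
              int hi = ho * stride - pad + ik;
              if (hi < 0 || hi >= H) continue;
              double v = xs[hi + H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          ys[ho + Ho * wo] = best;
          is[ho + Ho * wo] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dys = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* is = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int i = 0; i < Ho * Wo; ++i)
        if (is[i] >= 0) dxs[is[i]] += dys[i];
    }
  }
  return dx;
}

// Half-pixel-centre bilinear resampling (align_corners = FALSE convention).
static void bilin_coeff(int out, int in, int i, int& i0, int& i1,
                        double& w0, double& w1) {
  double s = (double)in / out;
  double src = (i + 0.5) * s - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, in - 1);
  w1 = src - i0;
  w0 = 1.0 - w1;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coeff(Ho, H, i, h0[i], h1[i], ha[i], hb[i]);
  for (int j = 0; j < Wo; ++j) bilin_coeff(Wo, W, j, w0i[j], w1i[j], wa[j], wb[j]);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          ys[i + Ho * j] =
            wa[j] * (ha[i] * xs[h0[i] + H * w0i[j]] +
                     hb[i] * xs[h1[i] + H * w0i[j]]) +
            wb[j] * (ha[i] * xs[h0[i] + H * w1i[j]] +
                     hb[i] * xs[h1[i] + H * w1i[j]]);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coeff(Ho, H, i, h0[i], h1[i], ha[i], hb[i]);
  for (int j = 0; j < Wo; ++j) bilin_coeff(Wo, W, j, w0i[j], w1i[j], wa[j], wb[j]);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dys = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double g = dys[i + Ho * j];
          dxs[h0[i] + H * w0i[j]] += wa[j] * ha[i] * g;
          dxs[h1[i] + H * w0i[j]] += wa[j] * hb[i] * g;
          dxs[h0[i] + H * w1i[j]] += wb[j] * ha[i] * g;
          dxs[h1[i] + H * w1i[j]] += wb[j] * hb[i] * g;
        }
      }
    }
  }
  return dx;
}
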