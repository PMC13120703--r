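#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are stored H x W x C x N (column-major, H fastest).
// Convolution weights are kh x kw x (Cin/groups) x Cout, so that collapsing
// the first three dims gives the im2col row ordering directly.
// All images of a minibatch share one GEMM: the unfolded patch matrix has
// K = kh*kw*(C/groups) rows and M*N columns (M = Ho*Wo output pixels).

static inline void im2col_batch(const double* x, int H, int W, int C, int N,
                                int kh, int kw, int stride, int pad,
                                int c0, int cg, int Ho, int Wo,
                                arma::mat& col) {
  const int M = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * H * W * C;
    for (int c = 0; c < cg; ++c) {
      const double* xc = xn + (size_t)(c0 + c) * H * W;
      for (int kwi = 0; kwi < kw; ++kwi) {
        for (int khi = 0; khi < kh; ++khi) {
          int row = khi + kh * (kwi + kw * c);
          double* dst = col.memptr() + row;
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * stride - pad + kwi;
            if (iw < 0 || iw >= W) {
              for (int oh = 0; oh < Ho; ++oh)
                dst[(size_t)col.n_rows * (oh + Ho * ow + (size_t)M * n)] = 0.0;
            } else {
              const double* xcol = xc + (size_t)iw * H;
              for (int oh = 0; oh < Ho; ++oh) {
                int ih = oh * stride - pad + khi;
                dst[(size_t)col.n_rows * (oh + Ho * ow + (size_t)M * n)] =
                    (ih >= 0 && ih < H) ? xcol[ih] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

static inline void col2im_batch(const arma::mat& col, double* gx,
                                int H, int W, int C, int N,
                                int kh, int kw, int stride, int pad,
                                int c0, int cg, int Ho, int Wo) {
  const int M = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    double* gn = gx + (size_t)n * H * W * C;
    for (int c = 0; c < cg; ++c) {
      double* gc = gn + (size_t)(c0 + c) * H * W;
      for (int kwi = 0; kwi < kw; ++kwi) {
        for (int khi = 0; khi < kh; ++khi) {
          int row = khi + kh * (kwi + kw * c);
          const double* src = col.memptr() + row;
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * stride - pad + kwi;
            if (iw < 0 || iw >= W) continue;
            double* gcol = gc + (size_t)iw * H;
            for (int oh = 0; oh < Ho; ++oh) {
              int ih = oh * stride - pad + khi;
              if (ih >= 0 && ih < H)
                gcol[ih] +=
                    src[(size_t)col.n_rows * (oh + Ho * ow + (size_t)M * n)];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  if (C != cg * groups) stop("channel/group mismatch in conv2d");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output extent would be empty");
  int coutg = Cout / groups;
  int K = kh * kw * cg, M = Ho * Wo;
  NumericVector y(static_cast<R_xlen_t>(M) * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wfull(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, (size_t)M * N);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad,
                 g * cg, cg, Ho, Wo, col);
    arma::mat Yall = col.t() * Wfull.cols(g * coutg, (g + 1) * coutg - 1);
    // Yall rows are (m, n); output wants y[m + M*(co + Cout*n)]
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < coutg; ++c) {
        std::memcpy(y.begin() + (size_t)M * (g * coutg + c + (size_t)Cout * n),
                    Yall.colptr(c) + (size_t)M * n, sizeof(double) * M);
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double bv = b[co];
        double* yp = y.begin() + (size_t)M * (co + (size_t)Cout * n);
        for (int m = 0; m < M; ++m) yp[m] += bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups, bool has_bias,
                    bool need_gx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int coutg = Cout / groups;
  int K = kh * kw * cg, M = Ho * Wo;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  arma::mat Wfull(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GWfull(gw.begin(), K, Cout, false, true);
  arma::mat col(K, (size_t)M * N);
  arma::mat Gall((size_t)M * N, coutg);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad,
                 g * cg, cg, Ho, Wo, col);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < coutg; ++c) {
        std::memcpy(Gall.colptr(c) + (size_t)M * n,
                    gy.begin() + (size_t)M * (g * coutg + c + (size_t)Cout * n),
                    sizeof(double) * M);
      }
    }
    GWfull.cols(g * coutg, (g + 1) * coutg - 1) = col * Gall;
    if (need_gx) {
      arma::mat colg = Wfull.cols(g * coutg, (g + 1) * coutg - 1) * Gall.t();
      col2im_batch(colg, gx.begin(), H, W, C, N, kh, kw, stride, pad,
                   g * cg, cg, Ho, Wo);
    }
  }
  List out = List::create(Named("gx") = gx, Named("gw") = gw);
  if (has_bias) {
    NumericVector gb(Cout);
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double* gp = gy.begin() + (size_t)M * (co + (size_t)Cout * n);
        double s = 0; for (int m = 0; m < M; ++m) s += gp[m];
        gb[co] += s;
      }
    out["gb"] = gb;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  R_xlen_t M = (R_xlen_t)Ho * Wo * C * N;
  NumericVector y(M);
  IntegerVector arg(M); // linear index into the input plane (0-based, per n,c)
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)C * n) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -INFINITY; int bidx = -1;
          for (int kwi = 0; kwi < k; ++kwi) {
            int iw = ow * stride - pad + kwi;
            if (iw < 0 || iw >= W) continue;
            for (int khi = 0; khi < k; ++khi) {
              int ih = oh * stride - pad + khi;
              if (ih < 0 || ih >= H) continue;
              double v = xc[ih + (size_t)iw * H];
              if (v > best) { best = v; bidx = ih + iw * H; }
            }
          }
          R_xlen_t oi = (R_xlen_t)oh + (R_xlen_t)Ho * ow +
                        (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
          y[oi] = best; arg[oi] = bidx;
        }
    }
  return List::create(Named("y") = y, Named("arg") = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector arg,
                              IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gc = gx.begin() + (size_t)(c + (size_t)C * n) * H * W;
      R_xlen_t base = (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (R_xlen_t m = 0; m < (R_xlen_t)Ho * Wo; ++m) {
        int idx = arg[base + m];
        if (idx >= 0) gc[idx] += gy[base + m];
      }
    }
  return gx;
}

// [[Rcpp::export]]
IntegerVector cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  // return as two 16-bit halves to avoid signed overflow in R integers
  return IntegerVector::create((int)(crc & 0xFFFFu), (int)(crc >> 16));
}
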