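// Convolution kernels for the network layers.
//
// Tensor layout follows R column-major arrays of dim (H, W, C, N).
// Convolution weights have dim (kh, kw, Cin, Cout); convolutions are
// cross-correlations (deep-learning convention, no kernel flip).
// Transposed convolutions are expressed in R as the data-gradient of a
// forward convolution, so only conv forward / backward kernels live here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold one image (H, W, C) into a (kh*kw*C) x (Ho*Wo) matrix.
// Row index k = a + kh*(b + kw*c) matches the column-major flattening of
// a (kh, kw, Cin, Cout) weight array into (kh*kw*Cin) x Cout.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const int p = i + Ho * j;
      const int i0 = i * stride - pad;
      const int j0 = j * stride - pad;
      double* cp = col.colptr(p);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          const int jj = j0 + b;
          const bool jok = jj >= 0 && jj < W;
          for (int a = 0; a < kh; ++a) {
            const int ii = i0 + a;
            const int k = a + kh * (b + kw * c);
            cp[k] = (jok && ii >= 0 && ii < H) ? xc[ii + (std::size_t)H * jj] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-accumulate the columns back into an (H, W, C) image.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* x) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const int p = i + Ho * j;
      const int i0 = i * stride - pad;
      const int j0 = j * stride - pad;
      const double* cp = col.colptr(p);
      for (int c = 0; c < C; ++c) {
        double* xc = x + (std::size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          const int jj = j0 + b;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int ii = i0 + a;
            if (ii < 0 || ii >= H) continue;
            xc[ii + (std::size_t)H * jj] += cp[a + kh * (b + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector bias,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: input has %d channels, weight expects %d", C, Cin);
  const int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  const int K = kh * kw * Cin, P = Ho * Wo;

  NumericVector out((std::size_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat Yn(out.begin() + (std::size_t)n * P * Cout, P, Cout, false, true);
    Yn = col.t() * Wm;
    Yn.each_row() += bv;
  }
  return out;
}

// Backward pass; returns grads for input, weight and bias.
// want_gx = false skips the data gradient (first layer of a network).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad, bool want_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  const int K = kh * kw * Cin, P = Ho * Wo;

  NumericVector gw((std::size_t)K * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx;
  if (want_gx) {
    gx = NumericVector((std::size_t)H * W * C * N);
    gx.attr("dim") = xd;
  }

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::rowvec GB(gb.begin(), Cout, false, true);
  arma::mat col(K, P), gcol(K, P);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    arma::mat Gn(const_cast<double*>(gy.begin()) + (std::size_t)n * P * Cout,
                 P, Cout, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    GW += col * Gn;
    GB += arma::sum(Gn, 0);
    if (want_gx) {
      gcol = Wm * Gn.t();
      col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             gx.begin() + (std::size_t)n * H * W * C);
    }
  }
  if (want_gx) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// Data gradient alone, with an explicit input size: this is also the forward
// pass of a transposed convolution (out size = (P-1)*stride + k - 2*pad).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector gy, NumericVector w,
                                int stride, int pad, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  if ((int)wd[3] != Cout) stop("conv_bwd_data: channel mismatch");
  const int K = kh * kw * Cin, P = Ho * Wo;

  NumericVector gx((std::size_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gcol(K, P);

  for (int n = 0; n < N; ++n) {
    arma::mat Gn(const_cast<double*>(gy.begin()) + (std::size_t)n * P * Cout,
                 P, Cout, false, true);
    gcol = Wm * Gn.t();
    col2im(gcol, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
           gx.begin() + (std::size_t)n * H * W * Cin);
  }
  return gx;
}

// Weight gradient alone (used for transposed-convolution backward, where the
// roles of input and output gradient are exchanged).
// [[Rcpp::export]]
NumericVector cpp_conv_gw(NumericVector x, NumericVector gy,
                          int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector gw((std::size_t)K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    arma::mat Gn(const_cast<double*>(gy.begin()) + (std::size_t)n * P * Cout,
                 P, Cout, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    GW += col * Gn;
  }
  return gw;
}

// Max pooling with remembered argmax positions (1-based flat index into the
// input image plane of each channel/image).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);

  NumericVector out((std::size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int i0 = i * stride - pad, j0 = j * stride - pad;
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int b = 0; b < k; ++b) {
            const int jj = j0 + b;
            if (jj < 0 || jj >= W) continue;
            for (int a = 0; a < k; ++a) {
              const int ii = i0 + a;
              if (ii < 0 || ii >= H) continue;
              const double v = xc[ii + (std::size_t)H * jj];
              if (v > best) { best = v; bi = ii + H * jj; }
            }
          }
          // column-major output order is (i, j, c, n), matching o's walk
          o = (std::size_t)i + Ho * ((std::size_t)j + Wo * ((std::size_t)c + (std::size_t)C * n));
          out[o] = best;
          idx[o] = bi + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const std::size_t plane = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off_in = ((std::size_t)n * C + c) * plane;
      const std::size_t off_out = ((std::size_t)n * C + c) * Ho * Wo;
      for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p) {
        gx[off_in + idx[off_out + p] - 1] += gy[off_out + p];
      }
    }
  }
  return gx;
}

// Instance normalisation: per (channel, image) standardisation over the
// spatial plane, with affine gain/shift per channel.
// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericVector x, NumericVector gamma,
                      NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int m = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = xd; xhat.attr("dim") = xd;
  NumericVector invstd(C * N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (std::size_t)cn * m;
    double s = 0, s2 = 0;
    for (int i = 0; i < m; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    const double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    const double is = 1.0 / std::sqrt(v + eps);
    invstd[cn] = is;
    const double g = gamma[cn % C], b = beta[cn % C];
    double* hp = xhat.begin() + (std::size_t)cn * m;
    double* op = out.begin() + (std::size_t)cn * m;
    for (int i = 0; i < m; ++i) {
      hp[i] = (xp[i] - mu) * is;
      op[i] = g * hp[i] + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(NumericVector xhat, NumericVector invstd,
                      NumericVector gamma, NumericVector gy) {
  IntegerVector xd = xhat.attr("dim");
  const int m = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector gx(xhat.size());
  gx.attr("dim") = xd;
  NumericVector gg(C), gb(C);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* hp = xhat.begin() + (std::size_t)cn * m;
    const double* gp = gy.begin() + (std::size_t)cn * m;
    double* op = gx.begin() + (std::size_t)cn * m;
    const int c = cn % C;
    const double g = gamma[c], is = invstd[cn];
    double s1 = 0, s2 = 0, sb = 0, sg = 0;
    for (int i = 0; i < m; ++i) {
      const double d = gp[i] * g;
      s1 += d; s2 += d * hp[i];
      sb += gp[i]; sg += gp[i] * hp[i];
    }
    gb[c] += sb; gg[c] += sg;
    const double mu1 = s1 / m, mu2 = s2 / m;
    for (int i = 0; i < m; ++i) {
      op[i] = is * (gp[i] * g - mu1 - hp[i] * mu2);
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector gy, double slope) {
  NumericVector g(x.size());
  g.attr("dim") = gy.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    g[i] = x[i] > 0 ? gy[i] : slope * gy[i];
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_add_bias(NumericVector x, NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  const int m = xd[0] * xd[1], C = xd[2], N = xd[3];
  for (int cn = 0; cn < C * N; ++cn) {
    double* xp = x.begin() + (std::size_t)cn * m;
    const double b = bias[cn % C];
    for (int i = 0; i < m; ++i) xp[i] += b;
  }
  return x;
}

// Channel softmax over dim 3 of an (H, W, K, N) logit array.
// [[Rcpp::export]]
NumericVector cpp_softmax_channels(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int m = xd[0] * xd[1], K = xd[2], N = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  std::vector<const double*> xp(K);
  std::vector<double*> op(K);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      xp[k] = x.begin() + ((std::size_t)n * K + k) * m;
      op[k] = out.begin() + ((std::size_t)n * K + k) * m;
    }
    for (int i = 0; i < m; ++i) {
      double mx = xp[0][i];
      for (int k = 1; k < K; ++k) mx = std::max(mx, xp[k][i]);
      double den = 0;
      for (int k = 0; k < K; ++k) { op[k][i] = std::exp(xp[k][i] - mx); den += op[k][i]; }
      for (int k = 0; k < K; ++k) op[k][i] /= den;
    }
  }
  return out;
}
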