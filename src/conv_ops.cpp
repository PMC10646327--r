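// Low-level layer kernels for the conversion-friendly U-Net.
//
// Array convention (column-major, matching R):
//   feature maps  x : dim (H, W, C, N)    height, width, channels, batch
//   conv weights  w : dim (kh, kw, Cin, Cout), no bias anywhere
//
// All operators are direct loops over kernel taps with a contiguous inner
// index; see the note above conv2d_fwd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector &x, int &d1, int &d2, int &d3, int &d4,
                  const char *what) {
  SEXP dAttr = x.attr("dim");
  if (Rf_isNull(dAttr))
    stop("'%s' must be a 4-d array", what);
  IntegerVector d(dAttr);
  if (d.size() != 4)
    stop("'%s' must be a 4-d array", what);
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}


// Direct convolution on a zero-padded per-sample buffer. At the feature-map
// sizes this package targets, materializing im2col matrices costs more in
// memory traffic than the arithmetic itself; straight tap loops with a
// contiguous inner index vectorize well and stay in cache.

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, int pad) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N, "x");
  dims4(w, kh, kw, Cin, Cout, "w");
  if (Cin != C)
    stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1)
    stop("conv2d: kernel larger than padded input");
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> xpad((size_t)Hp * Wp * C, 0.0);
  NumericVector y((long)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *xp = REAL(x);
  const double *wp = REAL(w);
  double *yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    if (pad > 0) {
      std::fill(xpad.begin(), xpad.end(), 0.0);
      for (int ci = 0; ci < C; ++ci)
        for (int j = 0; j < W; ++j)
          std::copy(xp + (long)H * (j + (long)W * (ci + (long)C * n)),
                    xp + (long)H * (j + (long)W * (ci + (long)C * n)) + H,
                    xpad.data() + (size_t)Hp * Wp * ci + pad +
                        (size_t)Hp * (j + pad));
    }
    for (int co = 0; co < Cout; ++co) {
      double *yplane = yp + (long)Ho * Wo * (co + (long)Cout * n);
      for (int ci = 0; ci < C; ++ci) {
        const int ldx = pad > 0 ? Hp : H;
        const double *x0 =
            pad > 0 ? xpad.data() + (size_t)Hp * Wp * ci
                    : xp + (long)H * W * (ci + (long)C * n);
        for (int dw = 0; dw < kw; ++dw)
          for (int dh = 0; dh < kh; ++dh) {
            const double wv = wp[dh + kh * (dw + kw * ((long)ci + C * co))];
            for (int wo = 0; wo < Wo; ++wo) {
              const double *src = x0 + dh + (long)ldx * (wo + dw);
              double *dst = yplane + (long)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) dst[ho] += wv * src[ho];
            }
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int pad) {
  int H, W, C, N, kh, kw, Cin, Cout, Ho, Wo, Cdy, Ndy;
  dims4(x, H, W, C, N, "x");
  dims4(w, kh, kw, Cin, Cout, "w");
  dims4(dy, Ho, Wo, Cdy, Ndy, "dy");
  if (Cin != C || Cdy != Cout || Ndy != N)
    stop("conv2d backward: inconsistent shapes");
  if (Ho != H + 2 * pad - kh + 1 || Wo != W + 2 * pad - kw + 1)
    stop("conv2d backward: 'dy' spatial size does not match");
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> xpad((size_t)Hp * Wp * C, 0.0);
  std::vector<double> dxpad((size_t)Hp * Wp * C, 0.0);
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((long)kh * kw * C * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  const double *xp = REAL(x);
  const double *wp = REAL(w);
  const double *dp = REAL(dy);
  double *dxp = REAL(dx);
  double *dwp = REAL(dw);
  for (int n = 0; n < N; ++n) {
    std::fill(xpad.begin(), xpad.end(), 0.0);
    std::fill(dxpad.begin(), dxpad.end(), 0.0);
    for (int ci = 0; ci < C; ++ci)
      for (int j = 0; j < W; ++j)
        std::copy(xp + (long)H * (j + (long)W * (ci + (long)C * n)),
                  xp + (long)H * (j + (long)W * (ci + (long)C * n)) + H,
                  xpad.data() + (size_t)Hp * Wp * ci + pad +
                      (size_t)Hp * (j + pad));
    for (int co = 0; co < Cout; ++co) {
      const double *dyplane = dp + (long)Ho * Wo * (co + (long)Cout * n);
      for (int ci = 0; ci < C; ++ci) {
        const double *x0 = xpad.data() + (size_t)Hp * Wp * ci;
        double *dx0 = dxpad.data() + (size_t)Hp * Wp * ci;
        for (int dw_ = 0; dw_ < kw; ++dw_)
          for (int dh = 0; dh < kh; ++dh) {
            const long widx = dh + kh * (dw_ + kw * ((long)ci + C * co));
            const double wv = wp[widx];
            double acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const double *src = x0 + dh + (long)Hp * (wo + dw_);
              double *ddst = dx0 + dh + (long)Hp * (wo + dw_);
              const double *dsrc = dyplane + (long)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                ddst[ho] += wv * dsrc[ho];
                acc += src[ho] * dsrc[ho];
              }
            }
            dwp[widx] += acc;
          }
      }
    }
    for (int ci = 0; ci < C; ++ci)
      for (int j = 0; j < W; ++j)
        std::copy(dxpad.data() + (size_t)Hp * Wp * ci + pad +
                      (size_t)Hp * (j + pad),
                  dxpad.data() + (size_t)Hp * Wp * ci + pad +
                      (size_t)Hp * (j + pad) + H,
                  dxp + (long)H * (j + (long)W * (ci + (long)C * n)));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".avgpool2_fwd")]]
NumericVector avgpool2_fwd_cpp(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N, "x");
  if (H % 2 || W % 2)
    stop("avgpool2: spatial dimensions must be even (got %d x %d)", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *xs = xp + cn * H * W;
    double *ys = yp + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *c0 = xs + 2 * ho + H * (2 * wo);
        ys[ho + Ho * wo] = 0.25 * (c0[0] + c0[1] + c0[H] + c0[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
NumericVector avgpool2_bwd_cpp(NumericVector dy) {
  int Ho, Wo, C, N;
  dims4(dy, Ho, Wo, C, N, "dy");
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dp = REAL(dy);
  double *xp = REAL(dx);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *ds = dp + cn * Ho * Wo;
    double *xs = xp + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * ds[ho + Ho * wo];
        double *c0 = xs + 2 * ho + H * (2 * wo);
        c0[0] = g; c0[1] = g; c0[H] = g; c0[H + 1] = g;
      }
  }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (exact 2x upsampling).
// y[2i+a, 2j+b, co, n] = sum_ci x[i, j, ci, n] * w[a, b, ci, co]
// [[Rcpp::export(name = ".upconv2_fwd")]]
NumericVector upconv2_fwd_cpp(NumericVector x, NumericVector w) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N, "x");
  dims4(w, kh, kw, Cin, Cout, "w");
  if (kh != 2 || kw != 2 || Cin != C)
    stop("upconv2: weights must have shape (2, 2, Cin, Cout) with Cin = %d", C);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((long)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *xp = REAL(x);
  const double *wp = REAL(w);
  double *yp = REAL(y);
  std::fill(yp, yp + y.size(), 0.0);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *ys = yp + (long)Ho * Wo * (co + (long)Cout * n);
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = xp + (long)H * W * (ci + (long)C * n);
        const double w00 = wp[0 + 2 * 0 + 4 * (ci + C * co)];
        const double w10 = wp[1 + 2 * 0 + 4 * (ci + C * co)];
        const double w01 = wp[0 + 2 * 1 + 4 * (ci + C * co)];
        const double w11 = wp[1 + 2 * 1 + 4 * (ci + C * co)];
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xs[i + H * j];
            double *c0 = ys + 2 * i + Ho * (2 * j);
            c0[0] += v * w00;
            c0[1] += v * w10;
            c0[Ho] += v * w01;
            c0[Ho + 1] += v * w11;
          }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upconv2_bwd")]]
List upconv2_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N, kh, kw, Cin, Cout, Ho, Wo, Cdy, Ndy;
  dims4(x, H, W, C, N, "x");
  dims4(w, kh, kw, Cin, Cout, "w");
  dims4(dy, Ho, Wo, Cdy, Ndy, "dy");
  if (kh != 2 || kw != 2 || Cin != C || Cdy != Cout || Ndy != N ||
      Ho != 2 * H || Wo != 2 * W)
    stop("upconv2 backward: inconsistent shapes");
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((long)4 * C * Cout);
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  const double *xp = REAL(x);
  const double *wp = REAL(w);
  const double *dp = REAL(dy);
  double *dxp = REAL(dx);
  double *dwp = REAL(dw);
  std::fill(dxp, dxp + dx.size(), 0.0);
  std::fill(dwp, dwp + dw.size(), 0.0);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *ds = dp + (long)Ho * Wo * (co + (long)Cout * n);
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = xp + (long)H * W * (ci + (long)C * n);
        double *dxs = dxp + (long)H * W * (ci + (long)C * n);
        const double w00 = wp[0 + 4 * (ci + C * co)];
        const double w10 = wp[1 + 4 * (ci + C * co)];
        const double w01 = wp[2 + 4 * (ci + C * co)];
        const double w11 = wp[3 + 4 * (ci + C * co)];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double *c0 = ds + 2 * i + Ho * (2 * j);
            const double d00 = c0[0], d10 = c0[1], d01 = c0[Ho],
                         d11 = c0[Ho + 1];
            dxs[i + H * j] += d00 * w00 + d10 * w10 + d01 * w01 + d11 * w11;
            const double v = xs[i + H * j];
            g00 += v * d00; g10 += v * d10; g01 += v * d01; g11 += v * d11;
          }
        dwp[0 + 4 * (ci + C * co)] += g00;
        dwp[1 + 4 * (ci + C * co)] += g10;
        dwp[2 + 4 * (ci + C * co)] += g01;
        dwp[3 + 4 * (ci + C * co)] += g11;
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Fused IF-neuron helpers: one pass over the layer instead of several
// vectorized R temporaries.

// integrate + fire + soft reset (+ optional dropout mask on the transmitted
// spikes). Returns the pre-reset membrane m, transmitted spikes s and the
// carried potential u'.
// [[Rcpp::export(name = ".if_fused_step")]]
List if_fused_step_cpp(NumericVector u, NumericVector z, double v,
                       Nullable<NumericVector> mask) {
  const R_xlen_t n = u.size();
  if (z.size() != n) stop("IF step: shape mismatch");
  NumericVector m(n), s(n), un(n);
  const double *up = REAL(u), *zp = REAL(z);
  double *mp = REAL(m), *sp = REAL(s), *unp = REAL(un);
  double spike_sum = 0.0;
  if (mask.isNotNull()) {
    NumericVector mk(mask);
    const double *kp = REAL(mk);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double mi = up[i] + zp[i];
      const bool f = mi > v;
      mp[i] = mi;
      unp[i] = f ? mi - v : mi;
      spike_sum += f;
      sp[i] = f ? kp[i] : 0.0;
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      const double mi = up[i] + zp[i];
      const bool f = mi > v;
      mp[i] = mi;
      unp[i] = f ? mi - v : mi;
      spike_sum += f;
      sp[i] = f ? 1.0 : 0.0;
    }
  }
  m.attr("dim") = u.attr("dim");
  s.attr("dim") = u.attr("dim");
  un.attr("dim") = u.attr("dim");
  return List::create(_["m"] = m, _["s"] = s, _["u"] = un,
                      _["nspikes"] = spike_sum);
}

// backward of the fused step: dm = ds*mask*g + dcarry*(1 - v*g) with
// g = alpha * max(0, 1 - |m - v|)
// [[Rcpp::export(name = ".if_fused_back")]]
NumericVector if_fused_back_cpp(NumericVector m, NumericVector ds,
                                NumericVector dcarry, double v, double alpha,
                                Nullable<NumericVector> mask) {
  const R_xlen_t n = m.size();
  NumericVector dm(n);
  const double *mp = REAL(m), *dsp = REAL(ds), *dcp = REAL(dcarry);
  double *dmp = REAL(dm);
  const double *kp = nullptr;
  NumericVector mk;
  if (mask.isNotNull()) { mk = NumericVector(mask); kp = REAL(mk); }
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = 1.0 - std::fabs(mp[i] - v);
    const double g = a > 0 ? alpha * a : 0.0;
    const double dsi = kp ? dsp[i] * kp[i] : dsp[i];
    dmp[i] = dsi * g + dcp[i] * (1.0 - v * g);
  }
  dm.attr("dim") = m.attr("dim");
  return dm;
}

// channel-axis concatenation / split for (H, W, C, N) maps
// [[Rcpp::export(name = ".channel_cat")]]
NumericVector channel_cat_cpp(NumericVector a, NumericVector b) {
  int H, W, Ca, N, H2, W2, Cb, N2;
  dims4(a, H, W, Ca, N, "a");
  dims4(b, H2, W2, Cb, N2, "b");
  if (H != H2 || W != W2 || N != N2) stop("channel_cat: shape mismatch");
  NumericVector out((long)H * W * (Ca + Cb) * N);
  out.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  const long plane = (long)H * W;
  double *op = REAL(out);
  const double *ap = REAL(a), *bp = REAL(b);
  for (int n = 0; n < N; ++n) {
    std::copy(ap + plane * (long)Ca * n, ap + plane * (long)Ca * (n + 1),
              op + plane * (long)(Ca + Cb) * n);
    std::copy(bp + plane * (long)Cb * n, bp + plane * (long)Cb * (n + 1),
              op + plane * ((long)(Ca + Cb) * n + Ca));
  }
  return out;
}

// [[Rcpp::export(name = ".channel_split")]]
List channel_split_cpp(NumericVector x, int c1) {
  int H, W, C, N;
  dims4(x, H, W, C, N, "x");
  if (c1 < 1 || c1 >= C) stop("channel_split: invalid split point");
  const int c2 = C - c1;
  NumericVector a((long)H * W * c1 * N), b((long)H * W * c2 * N);
  a.attr("dim") = IntegerVector::create(H, W, c1, N);
  b.attr("dim") = IntegerVector::create(H, W, c2, N);
  const long plane = (long)H * W;
  const double *xp = REAL(x);
  for (int n = 0; n < N; ++n) {
    std::copy(xp + plane * (long)C * n, xp + plane * ((long)C * n + c1),
              REAL(a) + plane * (long)c1 * n);
    std::copy(xp + plane * ((long)C * n + c1), xp + plane * (long)C * (n + 1),
              REAL(b) + plane * (long)c2 * n);
  }
  return List::create(a, b);
}
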