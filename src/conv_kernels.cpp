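// Convolution kernels for the autodiff engine.
// Layout: images are arma::cube-compatible arrays with R dim (H, W, C) per
// sample; batches are passed as 4-d arrays dim (H, W, C, N) flattened
// column-major (native R array order). Weights: dim (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col: (H, W, Cin) -> (kh*kw*Cin) x (Ho*Wo), zero padding, stride s.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int p, int Ho, int Wo, mat& cols) {
  cols.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int rowbase = c * kh * kw + dj * kh + di;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          const double* xcj = xc + (size_t)j * H;
          double* col = cols.memptr() + (size_t)(oj * Ho) * cols.n_rows + rowbase;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * s + di - p;
            if (i < 0 || i >= H) continue;
            col[(size_t)oi * cols.n_rows] = xcj[i];
          }
        }
      }
    }
  }
}

// col2im: adjoint of im2col (accumulates).
static void col2im(const mat& cols, int H, int W, int C,
                   int kh, int kw, int s, int p, int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int rowbase = c * kh * kw + dj * kh + di;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          double* xcj = xc + (size_t)j * H;
          const double* col = cols.memptr() + (size_t)(oj * Ho) * cols.n_rows + rowbase;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * s + di - p;
            if (i < 0 || i >= H) continue;
            xcj[i] += col[(size_t)oi * cols.n_rows];
          }
        }
      }
    }
  }
}

static inline int outdim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                               int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("channel mismatch");
  int Ho = outdim(H, kh, stride, pad), Wo = outdim(W, kw, stride, pad);
  Rcpp::NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    mat o(out.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    o = cols.t() * Wm;
  }
  return out;
}

// gradient w.r.t. input: "transposed convolution" of gradout with w.
// [[Rcpp::export]]
Rcpp::NumericVector conv2d_bwd_input(Rcpp::NumericVector gout, Rcpp::NumericVector w,
                                     int stride, int pad, int H, int W) {
  Rcpp::IntegerVector gd = gout.attr("dim"), wd = w.attr("dim");
  int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  Rcpp::NumericVector out((size_t)H * W * Cin * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, Cin, N);
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    mat g(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    mat cols = Wm * g.t();
    col2im(cols, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
           out.begin() + (size_t)n * H * W * Cin);
  }
  return out;
}

// gradient w.r.t. weights.
// [[Rcpp::export]]
Rcpp::NumericVector conv2d_bwd_weight(Rcpp::NumericVector x, Rcpp::NumericVector gout,
                                      int stride, int pad, int kh, int kw) {
  Rcpp::IntegerVector xd = x.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  Rcpp::NumericVector out((size_t)kh * kw * C * Cout);
  out.attr("dim") = Rcpp::IntegerVector::create(kh, kw, C, Cout);
  mat acc(kh * kw * C, Cout, fill::zeros);
  mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    mat g(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    acc += cols * g;
  }
  std::copy(acc.begin(), acc.end(), out.begin());
  return out;
}

// ---- group normalization ----------------------------------------------------
// x: (H, W, C, N); gamma/beta length C; groups divides C.
// [[Rcpp::export]]
Rcpp::List gn_fwd(Rcpp::NumericVector x, Rcpp::NumericVector gamma,
                  Rcpp::NumericVector beta, int groups, double eps) {
  Rcpp::IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int cg = C / groups;
  size_t m = (size_t)H * W * cg;
  Rcpp::NumericVector out(x.size());
  out.attr("dim") = xd;
  Rcpp::NumericMatrix mu(groups, N), istd(groups, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int gidx = 0; gidx < groups; ++gidx) {
      const double* xg = xp + ((size_t)n * C + (size_t)gidx * cg) * H * W;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < m; ++i) { s += xg[i]; s2 += xg[i] * xg[i]; }
      double mean = s / m;
      double var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      double is = 1.0 / std::sqrt(var + eps);
      mu(gidx, n) = mean; istd(gidx, n) = is;
      double* og = op + ((size_t)n * C + (size_t)gidx * cg) * H * W;
      for (int c = 0; c < cg; ++c) {
        double ga = gamma[gidx * cg + c], be = beta[gidx * cg + c];
        const double* xc = xg + (size_t)c * H * W;
        double* oc = og + (size_t)c * H * W;
        for (size_t i = 0; i < (size_t)H * W; ++i)
          oc[i] = (xc[i] - mean) * is * ga + be;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("mu") = mu,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List gn_bwd(Rcpp::NumericVector x, Rcpp::NumericVector g,
                  Rcpp::NumericVector gamma, Rcpp::NumericMatrix mu,
                  Rcpp::NumericMatrix istd, int groups) {
  Rcpp::IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int cg = C / groups;
  size_t hw = (size_t)H * W, m = hw * cg;
  Rcpp::NumericVector dx(x.size());
  dx.attr("dim") = xd;
  Rcpp::NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    for (int gidx = 0; gidx < groups; ++gidx) {
      size_t base = ((size_t)n * C + (size_t)gidx * cg) * hw;
      const double* xg = x.begin() + base;
      const double* gg = g.begin() + base;
      double* dxg = dx.begin() + base;
      double mean = mu(gidx, n), is = istd(gidx, n);
      // accumulate means of dxhat and dxhat*xhat over the group
      double s1 = 0, s2 = 0;
      for (int c = 0; c < cg; ++c) {
        double ga = gamma[gidx * cg + c];
        const double* xc = xg + (size_t)c * hw;
        const double* gc = gg + (size_t)c * hw;
        double dga = 0, dbe = 0;
        for (size_t i = 0; i < hw; ++i) {
          double xh = (xc[i] - mean) * is;
          double dxh = gc[i] * ga;
          s1 += dxh; s2 += dxh * xh;
          dga += gc[i] * xh; dbe += gc[i];
        }
        dgamma[gidx * cg + c] += dga;
        dbeta[gidx * cg + c] += dbe;
      }
      s1 /= m; s2 /= m;
      for (int c = 0; c < cg; ++c) {
        double ga = gamma[gidx * cg + c];
        const double* xc = xg + (size_t)c * hw;
        const double* gc = gg + (size_t)c * hw;
        double* dc = dxg + (size_t)c * hw;
        for (size_t i = 0; i < hw; ++i) {
          double xh = (xc[i] - mean) * is;
          dc[i] = (gc[i] * ga - s1 - xh * s2) * is;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// ---- SiLU -------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::NumericVector silu_fwd(Rcpp::NumericVector x) {
  Rcpp::NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    out[i] = x[i] * s;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector silu_bwd(Rcpp::NumericVector x, Rcpp::NumericVector g) {
  Rcpp::NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    out[i] = g[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return out;
}

// ---- channel bias broadcast (C, N) over (H, W, C, N) ------------------------
// [[Rcpp::export]]
Rcpp::NumericVector bias_cn_fwd(Rcpp::NumericVector x, Rcpp::NumericMatrix b) {
  Rcpp::IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1];
  Rcpp::NumericVector out(x.size());
  out.attr("dim") = xd;
  size_t idx = 0;
  for (int n = 0; n < xd[3]; ++n)
    for (int c = 0; c < xd[2]; ++c) {
      double bv = b(c, n);
      for (size_t i = 0; i < hw; ++i, ++idx) out[idx] = x[idx] + bv;
    }
  return out;
}
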