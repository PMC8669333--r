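// Minimal 2-D convolution kernels for the CPU training engine.
// Layout follows R column-major arrays: x is (H, W, Cin, N),
// w is (kh, kw, Cin, Cout), outputs (Ho, Wo, Cout, N).
// im2col column index u + kh*(v + kw*c) matches the flattening of w
// into a (kh*kw*Cin) x Cout matrix, so forward is one GEMM per sample.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Map a (possibly out-of-frame) padded index onto the source frame.
// mode 0: zero padding (-1 marks "outside"); mode 1: mirror without
// edge repetition (reflect-101), valid while pad <= size - 1.
static inline int map_idx(int i, int n, int mode) {
  if (i >= 0 && i < n) return i;
  if (mode == 0) return -1;
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  if (i < 0 || i >= n) return -1; // degenerate tiny inputs
  return i;
}

static void build_maps(int H, int W, int Ho, int Wo, int kh, int kw,
                       int stride, int pad, int mode,
                       std::vector<int>& rmap, std::vector<int>& cmap) {
  rmap.resize((size_t)Ho * kh);
  cmap.resize((size_t)Wo * kw);
  for (int i = 0; i < Ho; ++i)
    for (int u = 0; u < kh; ++u)
      rmap[(size_t)i * kh + u] = map_idx(i * stride - pad + u, H, mode);
  for (int j = 0; j < Wo; ++j)
    for (int v = 0; v < kw; ++v)
      cmap[(size_t)j * kw + v] = map_idx(j * stride - pad + v, W, mode);
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad, int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch between input and weights");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  std::vector<int> rmap, cmap;
  build_maps(H, W, Ho, Wo, kh, kw, stride, pad, pad_mode, rmap, cmap);

  const arma::mat W2(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat M((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t xs = (size_t)H * W * Cin, ys = (size_t)Ho * Wo * Cout;

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + n * xs;
    M.zeros();
    for (int c = 0; c < Cin; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int v = 0; v < kw; ++v)
        for (int u = 0; u < kh; ++u) {
          const size_t col = (size_t)u + kh * ((size_t)v + kw * c);
          double* Mcol = M.colptr(col);
          for (int j = 0; j < Wo; ++j) {
            const int sc = cmap[(size_t)j * kw + v];
            if (sc < 0) continue;
            const double* xcc = xc + (size_t)sc * H;
            double* Mj = Mcol + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) {
              const int sr = rmap[(size_t)i * kh + u];
              if (sr >= 0) Mj[i] = xcc[sr];
            }
          }
        }
    }
    arma::mat Y(yp + n * ys, (size_t)Ho * Wo, Cout, false, true);
    Y = M * W2;
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  std::vector<int> rmap, cmap;
  build_maps(H, W, Ho, Wo, kh, kw, stride, pad, pad_mode, rmap, cmap);

  const arma::mat W2(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  arma::mat gW2((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);

  arma::mat M((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  const size_t xs = (size_t)H * W * Cin, ys = (size_t)Ho * Wo * Cout;

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + n * xs;
    M.zeros();
    for (int c = 0; c < Cin; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int v = 0; v < kw; ++v)
        for (int u = 0; u < kh; ++u) {
          const size_t col = (size_t)u + kh * ((size_t)v + kw * c);
          double* Mcol = M.colptr(col);
          for (int j = 0; j < Wo; ++j) {
            const int sc = cmap[(size_t)j * kw + v];
            if (sc < 0) continue;
            const double* xcc = xc + (size_t)sc * H;
            double* Mj = Mcol + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) {
              const int sr = rmap[(size_t)i * kh + u];
              if (sr >= 0) Mj[i] = xcc[sr];
            }
          }
        }
    }
    const arma::mat Gy(const_cast<double*>(gp) + n * ys, (size_t)Ho * Wo, Cout, false);
    gW2 += M.t() * Gy;
    gb += arma::sum(Gy, 0).t();
    arma::mat gM = Gy * W2.t();
    double* gxn = gxp + n * xs;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxn + (size_t)c * H * W;
      for (int v = 0; v < kw; ++v)
        for (int u = 0; u < kh; ++u) {
          const size_t col = (size_t)u + kh * ((size_t)v + kw * c);
          const double* Gcol = gM.colptr(col);
          for (int j = 0; j < Wo; ++j) {
            const int sc = cmap[(size_t)j * kw + v];
            if (sc < 0) continue;
            double* gxcc = gxc + (size_t)sc * H;
            const double* Gj = Gcol + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) {
              const int sr = rmap[(size_t)i * kh + u];
              if (sr >= 0) gxcc[sr] += Gj[i];
            }
          }
        }
    }
  }

  NumericVector gwv(gW2.memptr(), gW2.memptr() + gW2.n_elem);
  gwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
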