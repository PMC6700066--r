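// im2col/GEMM 2D convolution forward and backward passes, plus leaky-ReLU
// kernels (the two hot spots of the training loop).
//
// Tensors are R arrays in (H, W, C, B) layout (column-major, so the memory
// order matches an Armadillo cube (H rows, W cols, C slices) per sample).
// Weights are (k, k, Cin, Cout); convolution is stride 1 with zero "same"
// padding and odd kernel size. The whole batch is lowered into one tall
// im2col matrix so each pass costs a single GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// fill rows [s*H*W, (s+1)*H*W) of the tall im2col matrix for one sample
static void im2col_into(const double* x, int H, int W, int C, int k,
                        mat& Xc, size_t row0) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int col = (di + p) + k * (dj + p) + k * k * c;
        double* dst = Xc.colptr(col) + row0;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double* src = xc + (size_t)H * js;
          double* d = dst + (size_t)H * j;
          for (int i = i0; i < i1; ++i) d[i] = src[i + di];
        }
      }
    }
  }
}

static void col2im_from(const mat& Xc, size_t row0, int H, int W, int C,
                        int k, double* dx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int col = (di + p) + k * (dj + p) + k * k * c;
        const double* src = Xc.colptr(col) + row0;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double* d = xc + (size_t)H * js;
          const double* s = src + (size_t)H * j;
          for (int i = i0; i < i1; ++i) d[i + di] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                               Rcpp::NumericVector b) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) Rcpp::stop("channel mismatch");
  const size_t HW = (size_t)H * W;
  mat Wm(w.begin(), k * k * C, Cout, false);
  rowvec bv(b.begin(), Cout);

  mat Xc(HW * B, (size_t)k * k * C, fill::zeros);
  for (int s = 0; s < B; ++s)
    im2col_into(x.begin() + HW * C * s, H, W, C, k, Xc, HW * s);
  mat Y = Xc * Wm;
  Y.each_row() += bv;

  Rcpp::NumericVector y(HW * Cout * B);
  y.attr("dim") = Rcpp::IntegerVector::create(H, W, Cout, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(y.begin() + HW * Cout * s + HW * c,
                  Y.colptr(c) + HW * s, HW * sizeof(double));
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                      Rcpp::NumericVector dy, bool need_dx = true) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const size_t HW = (size_t)H * W;
  mat Wm(w.begin(), k * k * C, Cout, false);

  mat Xc(HW * B, (size_t)k * k * C, fill::zeros);
  for (int s = 0; s < B; ++s)
    im2col_into(x.begin() + HW * C * s, H, W, C, k, Xc, HW * s);

  mat dY(HW * B, Cout);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(dY.colptr(c) + HW * s,
                  dy.begin() + HW * Cout * s + HW * c, HW * sizeof(double));

  Rcpp::NumericVector dw((R_xlen_t)k * k * C * Cout);
  dw.attr("dim") = Rcpp::IntegerVector::create(k, k, C, Cout);
  mat dWm(dw.begin(), k * k * C, Cout, false, true);
  dWm = Xc.t() * dY;
  Rcpp::NumericVector db(Cout);
  rowvec dbv = sum(dY, 0);
  std::memcpy(db.begin(), dbv.memptr(), Cout * sizeof(double));

  if (!need_dx)
    return Rcpp::List::create(Rcpp::Named("dw") = dw, Rcpp::Named("db") = db);

  mat dXc = dY * Wm.t();
  Rcpp::NumericVector dx((R_xlen_t)HW * C * B);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  for (int s = 0; s < B; ++s)
    col2im_from(dXc, HW * s, H, W, C, k, dx.begin() + HW * C * s);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::NumericVector lrelu_fwd_cpp(Rcpp::NumericVector z, double slope) {
  Rcpp::NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  const double* zi = z.begin();
  double* yi = y.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i)
    yi[i] = zi[i] > 0 ? zi[i] : slope * zi[i];
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector lrelu_bwd_cpp(Rcpp::NumericVector z, Rcpp::NumericVector dy,
                                  double slope) {
  Rcpp::NumericVector g(dy.size());
  g.attr("dim") = dy.attr("dim");
  const double* zi = z.begin();
  const double* di = dy.begin();
  double* gi = g.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    gi[i] = zi[i] > 0 ? di[i] : slope * di[i];
  return g;
}
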