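// GEMM-based 2D convolution with dilation and stride ("same" padding rule),
// forward and backward. Feature maps are arma::cube (H x W x C), matching
// R arrays of dim c(H, W, C). Weights arrive as a flat vector with dim
// (k, k, Cin, Cout). The convolution is computed tap-by-tap: for each of the
// k*k kernel taps a shifted copy of the input is gathered into an
// (Ho*Wo x Cin) matrix and multiplied against the tap's (Cin x Cout) slab.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int n, int stride) {
  // Keras-style "same": ceil(n / stride)
  return (n + stride - 1) / stride;
}

static inline int pad_begin(int n, int k, int stride, int dilation) {
  int eff = dilation * (k - 1) + 1;
  int no = out_size(n, stride);
  int total = std::max((no - 1) * stride + eff - n, 0);
  return total / 2;
}

// Gather the shifted input for tap (ki, kj) into Xs (Ho*Wo x Cin).
static void gather_tap(const cube& x, mat& Xs, int ki, int kj,
                       int stride, int dilation, int ho, int wo,
                       int pad_h, int pad_w) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  Xs.zeros();
  for (int c = 0; c < cin; ++c) {
    const mat& xc = x.slice(c);
    for (int ox = 0; ox < wo; ++ox) {
      int ix = ox * stride - pad_w + kj * dilation;
      if (ix < 0 || ix >= w) continue;
      for (int oy = 0; oy < ho; ++oy) {
        int iy = oy * stride - pad_h + ki * dilation;
        if (iy < 0 || iy >= h) continue;
        Xs(oy + (size_t)ox * ho, c) = xc(iy, ix);
      }
    }
  }
}

// Scatter-add dXs (Ho*Wo x Cin) back into dx at the tap's positions.
static void scatter_tap(cube& dx, const mat& dXs, int ki, int kj,
                        int stride, int dilation, int ho, int wo,
                        int pad_h, int pad_w) {
  const int h = dx.n_rows, w = dx.n_cols, cin = dx.n_slices;
  for (int c = 0; c < cin; ++c) {
    mat& dc = dx.slice(c);
    for (int ox = 0; ox < wo; ++ox) {
      int ix = ox * stride - pad_w + kj * dilation;
      if (ix < 0 || ix >= w) continue;
      for (int oy = 0; oy < ho; ++oy) {
        int iy = oy * stride - pad_h + ki * dilation;
        if (iy < 0 || iy >= h) continue;
        dc(iy, ix) += dXs(oy + (size_t)ox * ho, c);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const Rcpp::NumericVector& w,
                      const arma::vec& b, int stride, int dilation) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin)
    Rcpp::stop("conv2d: input has %d channels, weight expects %d",
               (int)x.n_slices, cin);
  const int h = x.n_rows, wi = x.n_cols;
  const int ho = out_size(h, stride), wo = out_size(wi, stride);
  const int pad_h = pad_begin(h, k, stride, dilation);
  const int pad_w = pad_begin(wi, k, stride, dilation);

  mat Y(ho * (size_t)wo, cout, fill::zeros);
  mat Xs(ho * (size_t)wo, cin);
  mat Wt(cin, cout);
  const double* wp = w.begin();
  for (int ki = 0; ki < k; ++ki) {
    for (int kj = 0; kj < k; ++kj) {
      for (int c = 0; c < cin; ++c)
        for (int o = 0; o < cout; ++o)
          Wt(c, o) = wp[ki + (size_t)k * (kj + (size_t)k * (c + (size_t)cin * o))];
      gather_tap(x, Xs, ki, kj, stride, dilation, ho, wo, pad_h, pad_w);
      Y += Xs * Wt;
    }
  }
  Y.each_row() += b.t();
  cube out(ho, wo, cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const Rcpp::NumericVector& w,
                      const arma::cube& dy, int stride, int dilation) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int h = x.n_rows, wi = x.n_cols;
  const int ho = dy.n_rows, wo = dy.n_cols;
  const int pad_h = pad_begin(h, k, stride, dilation);
  const int pad_w = pad_begin(wi, k, stride, dilation);

  mat dY(ho * (size_t)wo, cout);
  std::memcpy(dY.memptr(), dy.memptr(), sizeof(double) * dY.n_elem);

  cube dx(h, wi, cin, fill::zeros);
  Rcpp::NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  double* dwp = dwv.begin();
  vec db = sum(dY, 0).t();

  mat Xs(ho * (size_t)wo, cin);
  mat Wt(cin, cout);
  const double* wp = w.begin();
  for (int ki = 0; ki < k; ++ki) {
    for (int kj = 0; kj < k; ++kj) {
      for (int c = 0; c < cin; ++c)
        for (int o = 0; o < cout; ++o)
          Wt(c, o) = wp[ki + (size_t)k * (kj + (size_t)k * (c + (size_t)cin * o))];
      gather_tap(x, Xs, ki, kj, stride, dilation, ho, wo, pad_h, pad_w);
      mat dWt = Xs.t() * dY;                    // Cin x Cout
      for (int c = 0; c < cin; ++c)
        for (int o = 0; o < cout; ++o)
          dwp[ki + (size_t)k * (kj + (size_t)k * (c + (size_t)cin * o))] = dWt(c, o);
      mat dXs = dY * Wt.t();                    // Ho*Wo x Cin
      scatter_tap(dx, dXs, ki, kj, stride, dilation, ho, wo, pad_h, pad_w);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dwv,
                            Rcpp::Named("db") = db);
}
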