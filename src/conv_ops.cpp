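// Convolution primitives for the hybrid counting network.
//
// Layout conventions (all column-major, matching R arrays):
//   activations : arma::cube  H x W x C
//   weights     : arma::mat   n_out x (C_in * k * k), tap order
//                 (ki fastest, then kj, then input channel)
//   patch matrix: (C_in * k * k) x (H * W), output pixel (i, j) in
//                 column j * H + i
//
// All convolutions are stride 1 with "same" zero padding; dilation d
// spaces the k x k taps d pixels apart, so the effective footprint side
// is k*d - d + 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = (k - 1) / 2;
  const int nr = C * k * k;
  mat cols(nr, (size_t)H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      const int oj = (kj - half) * d;
      for (int ki = 0; ki < k; ++ki) {
        const int oi = (ki - half) * d;
        const int row = c * k * k + kj * k + ki;
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc.colptr(j + oj);
          double* dst = cols.colptr((size_t)j * H);
          for (int i = i0; i < i1; ++i)
            dst[(size_t)i * nr + row] = src[i + oi];
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of cpp_im2col.
static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int k, int d) {
  const int half = (k - 1) / 2;
  const int nr = C * k * k;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      const int oj = (kj - half) * d;
      for (int ki = 0; ki < k; ++ki) {
        const int oi = (ki - half) * d;
        const int row = c * k * k + kj * k + ki;
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        for (int j = j0; j < j1; ++j) {
          double* dst = xc.colptr(j + oj);
          const double* src = cols.colptr((size_t)j * H);
          for (int i = i0; i < i1; ++i)
            dst[i + oi] += src[(size_t)i * nr + row];
        }
      }
    }
  }
  return x;
}

// Forward pass of one conv layer. Returns the (post-activation) output
// and, when keep_cols is true, the patch matrix needed by the backward
// pass.
// [[Rcpp::export]]
Rcpp::List cpp_conv_forward(const arma::cube& x, const arma::mat& Wm,
                            const arma::vec& b, int k, int d,
                            bool relu, bool keep_cols) {
  const int H = x.n_rows, W = x.n_cols;
  const uword nout = Wm.n_rows;
  mat cols = cpp_im2col(x, k, d);
  mat out = Wm * cols;
  out.each_col() += b;
  if (relu)
    out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube y(H, W, nout);
  for (uword c = 0; c < nout; ++c)
    y.slice(c) = reshape(out.row(c), H, W);
  if (keep_cols)
    return Rcpp::List::create(Rcpp::Named("out") = y,
                              Rcpp::Named("cols") = cols);
  return Rcpp::List::create(Rcpp::Named("out") = y);
}

// Backward pass. dy is the gradient w.r.t. the layer output; when the
// layer had a ReLU, y (the post-activation output) gates the gradient.
// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& dy, const arma::cube& y,
                             const arma::mat& cols, const arma::mat& Wm,
                             int k, int d, int c_in, bool relu,
                             bool need_dx) {
  const int H = dy.n_rows, W = dy.n_cols;
  const int nout = dy.n_slices;
  mat dyM(nout, (size_t)H * W);
  for (int c = 0; c < nout; ++c) {
    if (relu) {
      mat g = dy.slice(c) % conv_to<mat>::from(y.slice(c) > 0.0);
      dyM.row(c) = vectorise(g).t();
    } else {
      dyM.row(c) = vectorise(dy.slice(c)).t();
    }
  }
  mat dW = dyM * cols.t();
  vec db = sum(dyM, 1);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dcols = Wm.t() * dyM;
    res["dx"] = col2im(dcols, H, W, c_in, k, d);
  }
  return res;
}

// 2x2 stride-2 max pooling; H and W must be even. Returns the pooled
// cube and the (1-based) linear argmax index into each slice.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C);
  cube idx(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = xc(i0, j0);
        size_t bidx = (size_t)j0 * H + i0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = xc(i0 + di, j0 + dj);
            if (v > best) {
              best = v;
              bidx = (size_t)(j0 + dj) * H + (i0 + di);
            }
          }
        y(i, j, c) = best;
        idx(i, j, c) = (double)(bidx + 1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dy, const arma::cube& idx,
                                 int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    const mat& dyc = dy.slice(c);
    const mat& ic = idx.slice(c);
    for (uword q = 0; q < dyc.n_elem; ++q)
      dxc((size_t)ic(q) - 1) += dyc(q);
  }
  return dx;
}
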