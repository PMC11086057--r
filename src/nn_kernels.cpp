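// Low-level numerical kernels for the density-regression network.
// Feature maps are arma::cube with layout (H rows, W cols, C slices),
// matching R arrays of dim c(H, W, C).  All convolutions are stride 1.
//
// im2col layout: row index r = (c*kh + i)*kw + j for input channel c and
// kernel offset (i, j); column index = ow*Hout + oh (column-major over the
// output grid), so a row of the GEMM result reshapes directly into an
// (Hout x Wout) matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_dil(const cube& x, const int kh, const int kw,
                      const int pad, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  if (Hout < 1 || Wout < 1)
    Rcpp::stop("convolution kernel larger than padded input");
  mat cols((uword)(C * kh * kw), (uword)Hout * (uword)Wout, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int i = 0; i < kh; ++i) {
      const int oh0 = std::max(0, pad - i * dil);
      const int oh1 = std::min(Hout - 1, H - 1 + pad - i * dil);
      for (int j = 0; j < kw; ++j) {
        const int r = (c * kh + i) * kw + j;
        for (int ow = 0; ow < Wout; ++ow) {
          const int wi = ow - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          const double* src = xs.colptr(wi);
          double* dst = cols.colptr((uword)ow * Hout);
          for (int oh = oh0; oh <= oh1; ++oh)
            dst[(uword)oh * cols.n_rows + r] = src[oh - pad + i * dil];
        }
      }
    }
  }
  return cols;
}

static cube col2im_dil(const mat& dcols, const int H, const int W,
                       const int C, const int kh, const int kw,
                       const int pad, const int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int i = 0; i < kh; ++i) {
      const int oh0 = std::max(0, pad - i * dil);
      const int oh1 = std::min(Hout - 1, H - 1 + pad - i * dil);
      for (int j = 0; j < kw; ++j) {
        const int r = (c * kh + i) * kw + j;
        for (int ow = 0; ow < Wout; ++ow) {
          const int wi = ow - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          double* dst = xs.colptr(wi);
          const double* src = dcols.colptr((uword)ow * Hout);
          for (int oh = oh0; oh <= oh1; ++oh)
            dst[oh - pad + i * dil] += src[(uword)oh * dcols.n_rows + r];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int kh, const int kw,
                      const int pad, const int dil) {
  if ((int)W.n_cols != (int)x.n_slices * kh * kw)
    Rcpp::stop("conv weight shape does not match input channels");
  const int Hout = x.n_rows + 2 * pad - dil * (kh - 1);
  const int Wout = x.n_cols + 2 * pad - dil * (kw - 1);
  const mat cols = im2col_dil(x, kh, kw, pad, dil);
  mat out_mat = W * cols;
  out_mat.each_col() += b;
  cube out(Hout, Wout, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    out.slice(c) = reshape(out_mat.row(c), Hout, Wout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy, const int kh, const int kw,
                          const int pad, const int dil) {
  const int Hout = dy.n_rows, Wout = dy.n_cols;
  mat dy_mat(W.n_rows, (uword)Hout * Wout);
  for (uword c = 0; c < dy.n_slices; ++c)
    dy_mat.row(c) = vectorise(dy.slice(c)).t();
  const mat cols = im2col_dil(x, kh, kw, pad, dil);
  mat dW = dy_mat * cols.t();
  vec db = sum(dy_mat, 1);
  mat dcols = W.t() * dy_mat;
  cube dx = col2im_dil(dcols, x.n_rows, x.n_cols, x.n_slices,
                       kh, kw, pad, dil);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 stride-2 max pooling, ceil mode (a trailing odd row/col pools a
// partial window).  idx records the 0-based column-major argmax within the
// input slice, for the backward scatter.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube out(Ho, Wo, C);
  cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double best = -datum::inf;
        int bi = -1;
        for (int dj = 0; dj < 2; ++dj) {
          const int wj = 2 * ow + dj;
          if (wj >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int hi = 2 * oh + di;
            if (hi >= H) continue;
            const double v = xs(hi, wj);
            if (v > best) { best = v; bi = wj * H + hi; }
          }
        }
        out(oh, ow, c) = best;
        idx(oh, ow, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::cube& idx,
                            const int H, const int W) {
  cube dx(H, W, dy.n_slices, fill::zeros);
  for (uword c = 0; c < dy.n_slices; ++c) {
    mat& xs = dx.slice(c);
    const mat& ds = dy.slice(c);
    const mat& is = idx.slice(c);
    for (uword k = 0; k < ds.n_elem; ++k)
      xs((uword)is(k)) += ds(k);
  }
  return dx;
}

struct BilinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w0, w1;
};

static BilinWeights bilin_axis(const int n_in, const int n_out) {
  // half-pixel (align_corners = false) source coordinates, edge-clamped
  BilinWeights bw;
  bw.i0.resize(n_out); bw.i1.resize(n_out);
  bw.w0.resize(n_out); bw.w1.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    const int i0 = (int)std::floor(s);
    const int i1 = std::min(i0 + 1, n_in - 1);
    const double w1 = s - i0;
    bw.i0[o] = i0; bw.i1[o] = i1; bw.w0[o] = 1.0 - w1; bw.w1[o] = w1;
  }
  return bw;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, const int oh,
                               const int ow) {
  const BilinWeights by = bilin_axis(x.n_rows, oh);
  const BilinWeights bx = bilin_axis(x.n_cols, ow);
  cube out(oh, ow, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) {
    const mat& xs = x.slice(c);
    mat& os = out.slice(c);
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        os(i, j) =
          by.w0[i] * (bx.w0[j] * xs(by.i0[i], bx.i0[j]) +
                      bx.w1[j] * xs(by.i0[i], bx.i1[j])) +
          by.w1[i] * (bx.w0[j] * xs(by.i1[i], bx.i0[j]) +
                      bx.w1[j] * xs(by.i1[i], bx.i1[j]));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_bwd(const arma::cube& dy, const int ih,
                                   const int iw) {
  const BilinWeights by = bilin_axis(ih, dy.n_rows);
  const BilinWeights bx = bilin_axis(iw, dy.n_cols);
  cube dx(ih, iw, dy.n_slices, fill::zeros);
  for (uword c = 0; c < dy.n_slices; ++c) {
    const mat& ds = dy.slice(c);
    mat& xs = dx.slice(c);
    for (uword j = 0; j < dy.n_cols; ++j) {
      for (uword i = 0; i < dy.n_rows; ++i) {
        const double g = ds(i, j);
        xs(by.i0[i], bx.i0[j]) += by.w0[i] * bx.w0[j] * g;
        xs(by.i0[i], bx.i1[j]) += by.w0[i] * bx.w1[j] * g;
        xs(by.i1[i], bx.i0[j]) += by.w1[i] * bx.w0[j] * g;
        xs(by.i1[i], bx.i1[j]) += by.w1[i] * bx.w1[j] * g;
      }
    }
  }
  return dx;
}

// Separable valid-region correlation with a symmetric 1-D kernel k
// (rows pass then columns pass).  Output is (H-k+1) x (W-k+1).
// [[Rcpp::export]]
arma::mat cpp_sepconv_valid(const arma::mat& x, const arma::vec& k) {
  const int n = k.n_elem;
  const int Hv = x.n_rows - n + 1, Wv = x.n_cols - n + 1;
  if (Hv < 1 || Wv < 1) Rcpp::stop("window larger than image");
  mat tmp(Hv, x.n_cols, fill::zeros);
  for (int t = 0; t < n; ++t)
    tmp += k(t) * x.rows(t, t + Hv - 1);
  mat out(Hv, Wv, fill::zeros);
  for (int t = 0; t < n; ++t)
    out += k(t) * tmp.cols(t, t + Wv - 1);
  return out;
}

// Transpose (adjoint) of cpp_sepconv_valid: scatter a valid-region
// gradient back onto the H x W input grid.
// [[Rcpp::export]]
arma::mat cpp_sepconv_valid_t(const arma::mat& g, const arma::vec& k,
                              const int H, const int W) {
  const int n = k.n_elem;
  const int Hv = g.n_rows, Wv = g.n_cols;
  mat tmp(Hv, W, fill::zeros);
  for (int t = 0; t < n; ++t)
    tmp.cols(t, t + Wv - 1) += k(t) * g;
  mat out(H, W, fill::zeros);
  for (int t = 0; t < n; ++t)
    out.rows(t, t + Hv - 1) += k(t) * tmp;
  return out;
}
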