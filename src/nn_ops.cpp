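// Minimal single-image CNN primitives (channels-last H x W x C cubes).
// Convolutions use im2col + BLAS matmul; 3x3 kernels with zero padding 1,
// stride 1 throughout (the tiny backbones need nothing else).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for 3x3, pad 1, stride 1: rows = H*W positions, cols = 9*Cin
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        uword k = c * 9 + (uword)((dr + 1) * 3 + (dc + 1));
        for (uword j = 0; j < W; ++j) {
          int sj = (int)j + dc;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int si = (int)i + dr;
            if (si < 0 || si >= (int)H) continue;
            out(j * H + i, k) = xc((uword)si, (uword)sj);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col3
static cube col2im3(const mat& cols, uword H, uword W, uword C) {
  cube out(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& oc = out.slice(c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        uword k = c * 9 + (uword)((dr + 1) * 3 + (dc + 1));
        for (uword j = 0; j < W; ++j) {
          int sj = (int)j + dc;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int si = (int)i + dr;
            if (si < 0 || si >= (int)H) continue;
            oc((uword)si, (uword)sj) += cols(j * H + i, k);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  // w: (9*Cin) x Cout, b: Cout
  const uword H = x.n_rows, W = x.n_cols;
  if (w.n_rows != 9 * x.n_slices)
    Rcpp::stop("conv3_forward: weight rows do not match 9*Cin");
  mat cols = im2col3(x);
  mat y = cols * w;                 // (H*W) x Cout
  y.each_row() += b.t();
  cube out(H, W, w.n_cols);
  for (uword c = 0; c < w.n_cols; ++c)
    out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward")]]
Rcpp::List conv3_backward(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = w.n_cols;
  mat gy_mat(H * W, Cout);
  for (uword c = 0; c < Cout; ++c)
    gy_mat.col(c) = vectorise(gy.slice(c));
  mat cols = im2col3(x);
  mat gw = cols.t() * gy_mat;              // (9*Cin) x Cout
  vec gb = sum(gy_mat, 0).t();
  mat gcols = gy_mat * w.t();              // (H*W) x (9*Cin)
  cube gx = col2im3(gcols, H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("maxpool2: odd spatial size");
  cube y(H / 2, W / 2, C);
  ucube idx(H / 2, W / 2, C); // 0..3 position of max in the 2x2 window
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W / 2; ++j) {
      for (uword i = 0; i < H / 2; ++i) {
        double v00 = x(2 * i, 2 * j, c),   v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        double best = v00; uword k = 0;
        if (v10 > best) { best = v10; k = 1; }
        if (v01 > best) { best = v01; k = 2; }
        if (v11 > best) { best = v11; k = 3; }
        y(i, j, c) = best; idx(i, j, c) = k;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& gy, const arma::ucube& idx,
                             int H, int W) {
  const uword C = gy.n_slices;
  cube gx((uword)H, (uword)W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < gy.n_cols; ++j) {
      for (uword i = 0; i < gy.n_rows; ++i) {
        uword k = idx(i, j, c);
        uword ii = 2 * i + (k == 1 || k == 3 ? 1 : 0);
        uword jj = 2 * j + (k >= 2 ? 1 : 0);
        gx(ii, jj, c) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
arma::cube upsample2_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}
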