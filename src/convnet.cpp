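// Low-level numerical kernels for the convolutional restoration network and
// the windowed-statistics filters used by SSIM.  Images are arma::cube
// (height x width x channels); convolution kernels are stored as a matrix
// with one column per output channel and rows indexed by (di + k*dj + k*k*c).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat im2col(const cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat A(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            A(i + H * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int pad = (k - 1) / 2;
  const int Cout = W.n_cols;
  mat A = im2col(x, k, pad);
  mat Y = A * W;
  Y.each_row() += b.t();
  cube y(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(Y.col(c), H, Wd);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  const int pad = (k - 1) / 2;
  mat A = im2col(x, k, pad);
  mat Gy(H * Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    Gy.col(c) = vectorise(gy.slice(c));
  mat gW = A.t() * Gy;
  vec gb = sum(Gy, 0).t();
  // scatter the column-space gradient back onto input pixels (col2im)
  mat Gcols = Gy * W.t();  // (H*W) x (k*k*Cin)
  cube gx(H, Wd, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        for (int j = 0; j < Wd; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= Wd) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += Gcols(i + H * j, col);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H / 2, W / 2, C);
  ucube idx(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i) {
        double best = x(2 * i, 2 * j, c);
        unsigned int arg = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; arg = di + 2 * dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy) {
  const int h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  cube gx(2 * h, 2 * w, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const unsigned int a = idx(i, j, c);
        gx(2 * i + (a % 2), 2 * j + (a / 2), c) = gy(i, j, c);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// [[Rcpp::export]]
arma::mat avgpool2_mat(const arma::mat& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2;
  mat y(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      y(i, j) = 0.25 * (x(2 * i, 2 * j) + x(2 * i + 1, 2 * j) +
                        x(2 * i, 2 * j + 1) + x(2 * i + 1, 2 * j + 1));
  return y;
}

// [[Rcpp::export]]
arma::mat avgpool2_mat_adj(const arma::mat& gy) {
  const int H = gy.n_rows, W = gy.n_cols;
  mat gx(2 * H, 2 * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double v = 0.25 * gy(i, j);
      gx(2 * i, 2 * j) = v;
      gx(2 * i + 1, 2 * j) = v;
      gx(2 * i, 2 * j + 1) = v;
      gx(2 * i + 1, 2 * j + 1) = v;
    }
  return gx;
}

// Plain cross-correlation of a single-channel image with a small kernel.
// "valid" keeps only fully-overlapping positions; "full" (the adjoint of
// valid) zero-pads so every partial overlap is kept.

// [[Rcpp::export]]
arma::mat corr2_valid(const arma::mat& x, const arma::mat& k) {
  const int H = x.n_rows, W = x.n_cols, kh = k.n_rows, kw = k.n_cols;
  mat y(H - kh + 1, W - kw + 1, fill::zeros);
  for (int dj = 0; dj < kw; ++dj)
    for (int di = 0; di < kh; ++di)
      y += k(di, dj) * x.submat(di, dj, di + H - kh, dj + W - kw);
  return y;
}

// [[Rcpp::export]]
arma::mat corr2_full_adj(const arma::mat& g, const arma::mat& k) {
  // adjoint of corr2_valid with the same kernel
  const int h = g.n_rows, w = g.n_cols, kh = k.n_rows, kw = k.n_cols;
  mat gx(h + kh - 1, w + kw - 1, fill::zeros);
  for (int dj = 0; dj < kw; ++dj)
    for (int di = 0; di < kh; ++di)
      gx.submat(di, dj, di + h - 1, dj + w - 1) += k(di, dj) * g;
  return gx;
}

// [[Rcpp::export]]
arma::mat pad_replicate(const arma::mat& x, const int p) {
  const int H = x.n_rows, W = x.n_cols;
  mat y(H + 2 * p, W + 2 * p);
  for (int j = 0; j < W + 2 * p; ++j) {
    int sj = j - p; if (sj < 0) sj = 0; if (sj >= W) sj = W - 1;
    for (int i = 0; i < H + 2 * p; ++i) {
      int si = i - p; if (si < 0) si = 0; if (si >= H) si = H - 1;
      y(i, j) = x(si, sj);
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat pad_replicate_adj(const arma::mat& g, const int p) {
  const int Hp = g.n_rows, Wp = g.n_cols;
  const int H = Hp - 2 * p, W = Wp - 2 * p;
  mat gx(H, W, fill::zeros);
  for (int j = 0; j < Wp; ++j) {
    int sj = j - p; if (sj < 0) sj = 0; if (sj >= W) sj = W - 1;
    for (int i = 0; i < Hp; ++i) {
      int si = i - p; if (si < 0) si = 0; if (si >= H) si = H - 1;
      gx(si, sj) += g(i, j);
    }
  }
  return gx;
}
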