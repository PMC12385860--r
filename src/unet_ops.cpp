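// Dense kernels for the 3-D convolutional segmenter: im2col-based 3x3x3
// convolution (zero padding 1) forward/backward and 2x2x2 max pooling.
// Feature maps are stored as C x N matrices with N = nx*ny*nz and voxel
// order matching R arrays (x fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// col matrix layout: row = c*27 + ((dk+1)*3 + (dj+1))*3 + (di+1), col = voxel
static arma::mat build_col(const arma::mat& x, int nx, int ny, int nz) {
  const int C = x.n_rows;
  const arma::uword N = x.n_cols;
  arma::mat col(27 * C, N, arma::fill::zeros);
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int o = ((dk + 1) * 3 + (dj + 1)) * 3 + (di + 1);
        // shifted copy: col[c*27+o, (i,j,k)] = x[c, (i+di, j+dj, k+dk)]
        for (int k = 0; k < nz; ++k) {
          int ks = k + dk;
          if (ks < 0 || ks >= nz) continue;
          for (int j = 0; j < ny; ++j) {
            int js = j + dj;
            if (js < 0 || js >= ny) continue;
            int i0 = std::max(0, -di);
            int i1 = std::min(nx, nx - di);
            if (i0 >= i1) continue;
            arma::uword dst = (arma::uword)nx * (j + (arma::uword)ny * k);
            arma::uword src = (arma::uword)nx * (js + (arma::uword)ny * ks);
            for (int c = 0; c < C; ++c)
              for (int i = i0; i < i1; ++i)
                col(c * 27 + o, dst + i) = x(c, src + i + di);
          }
        }
      }
  return col;
}

// scatter-add transpose of build_col
static arma::mat scatter_col(const arma::mat& dcol, int C, int nx, int ny,
                             int nz) {
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat dx(C, N, arma::fill::zeros);
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int o = ((dk + 1) * 3 + (dj + 1)) * 3 + (di + 1);
        for (int k = 0; k < nz; ++k) {
          int ks = k + dk;
          if (ks < 0 || ks >= nz) continue;
          for (int j = 0; j < ny; ++j) {
            int js = j + dj;
            if (js < 0 || js >= ny) continue;
            int i0 = std::max(0, -di);
            int i1 = std::min(nx, nx - di);
            if (i0 >= i1) continue;
            arma::uword dst = (arma::uword)nx * (j + (arma::uword)ny * k);
            arma::uword src = (arma::uword)nx * (js + (arma::uword)ny * ks);
            for (int c = 0; c < C; ++c)
              for (int i = i0; i < i1; ++i)
                dx(c, src + i + di) += dcol(c * 27 + o, dst + i);
          }
        }
      }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3_forward_col(const arma::mat& x, const arma::mat& W,
                           const arma::vec& b, IntegerVector dim) {
  arma::mat col = build_col(x, dim[0], dim[1], dim[2]);
  arma::mat y = W * col;
  y.each_col() += b;
  return List::create(_["y"] = y, _["col"] = col);
}

// [[Rcpp::export]]
arma::mat cpp_conv3_forward(const arma::mat& x, const arma::mat& W,
                            const arma::vec& b, IntegerVector dim) {
  arma::mat col = build_col(x, dim[0], dim[1], dim[2]);
  arma::mat y = W * col;
  y.each_col() += b;
  return y;
}

// backward reusing the forward's col matrix (training path)
// [[Rcpp::export]]
List cpp_conv3_backward_col(const arma::mat& col, const arma::mat& W,
                            const arma::mat& dy, IntegerVector dim,
                            int c_in) {
  arma::mat dW = dy * col.t();
  arma::vec db = arma::sum(dy, 1);
  arma::mat dcol = W.t() * dy;
  arma::mat dx = scatter_col(dcol, c_in, dim[0], dim[1], dim[2]);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_conv3_backward(const arma::mat& x, const arma::mat& W,
                        const arma::mat& dy, IntegerVector dim) {
  arma::mat col = build_col(x, dim[0], dim[1], dim[2]);
  arma::mat dW = dy * col.t();
  arma::vec db = arma::sum(dy, 1);
  arma::mat dcol = W.t() * dy;
  arma::mat dx = scatter_col(dcol, x.n_rows, dim[0], dim[1], dim[2]);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling, stride 2 (dims must be even). Returns pooled map and
// the 1-based input column index of each winner for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::mat& x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int C = x.n_rows;
  const arma::uword NO = (arma::uword)ox * oy * oz;
  arma::mat y(C, NO);
  arma::umat arg(C, NO);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        arma::uword oidx = i + (arma::uword)ox * (j + (arma::uword)oy * k);
        for (int c = 0; c < C; ++c) {
          double best = -1e300;
          arma::uword bidx = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                arma::uword q = (2 * i + di) +
                                (arma::uword)nx * ((2 * j + dj) +
                                                   (arma::uword)ny * (2 * k + dk));
                double v = x(c, q);
                if (v > best) {
                  best = v;
                  bidx = q;
                }
              }
          y(c, oidx) = best;
          arg(c, oidx) = bidx + 1;
        }
      }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_backward(const arma::mat& dy, const arma::umat& arg,
                               int n_in) {
  const int C = dy.n_rows;
  arma::mat dx(C, n_in, arma::fill::zeros);
  for (arma::uword j = 0; j < dy.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dx(c, arg(c, j) - 1) += dy(c, j);
  return dx;
}
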