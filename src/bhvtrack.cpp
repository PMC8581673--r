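#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are stored channel-major: F is (c, h*w*n) with spatial index
// s = y + h*x inside each per-image block of h*w columns.  im2col unrolls
// k x k patches (stride, zero pad) into rows ch + c*(ky + k*kx) so that a
// convolution becomes W (oc, c*k*k) %*% cols.

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& F, int h, int w, int n, int k,
                     int stride, int pad) {
  const int c  = F.n_rows;
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  arma::mat out(c * k * k, (arma::uword)oh * ow * n, arma::fill::zeros);
  for (int img = 0; img < n; ++img) {
    const arma::uword fo = (arma::uword)img * h * w;
    const arma::uword co = (arma::uword)img * oh * ow;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const arma::uword col = co + (arma::uword)ox * oh + oy;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= h) continue;
            const arma::uword s = fo + (arma::uword)ix * h + iy;
            const int rbase = c * (ky + k * kx);
            for (int ch = 0; ch < c; ++ch) out(rbase + ch, col) = F(ch, s);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the input map.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& cols, int c, int h, int w, int n, int k,
                     int stride, int pad) {
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  arma::mat F(c, (arma::uword)h * w * n, arma::fill::zeros);
  for (int img = 0; img < n; ++img) {
    const arma::uword fo = (arma::uword)img * h * w;
    const arma::uword co = (arma::uword)img * oh * ow;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const arma::uword col = co + (arma::uword)ox * oh + oy;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= h) continue;
            const arma::uword s = fo + (arma::uword)ix * h + iy;
            const int rbase = c * (ky + k * kx);
            for (int ch = 0; ch < c; ++ch) F(ch, s) += cols(rbase + ch, col);
          }
        }
      }
    }
  }
  return F;
}

// 8-connected component labeling of a logical matrix (h x w, column-major).
// Labels are assigned in scan order (columns left to right, rows top to
// bottom within a column), so label ids are deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear();
      stack.push_back(y + h * x);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int px = p / h, py = p % h;
        for (int dx = -1; dx <= 1; ++dx) {
          const int nx = px + dx;
          if (nx < 0 || nx >= w) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dx && !dy) continue;
            const int ny = py + dy;
            if (ny < 0 || ny >= h) continue;
            if (mask(ny, nx) && !lab(ny, nx)) {
              lab(ny, nx) = next;
              stack.push_back(ny + h * nx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-row median of a (n_pixels x k) stack; used for temporal-median
// background estimation where an R apply() would be too slow.
// [[Rcpp::export]]
arma::vec cpp_row_median(const arma::mat& X) {
  return arma::median(X, 1);
}
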