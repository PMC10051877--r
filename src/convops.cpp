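#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Stride-1 "same" convolution primitives via im2col + GEMM.
// Tensors are R arrays in (H, W, C) column-major order; kernels are
// (k, k, Cin, Cout).  The im2col column index ki + k*kj + k*k*c matches the
// linear layout of the kernel array, so the kernel can be viewed directly as
// a (k*k*Cin) x Cout matrix without copying.

static arma::mat im2col_same(const arma::cube &x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            M(i + H * j, col) = x(ii, jj, c);
          }
        }
      }
    }
  }
  return M;
}

static arma::cube col2im_same(const arma::mat &Mg, int H, int W, int C, int k,
                              int pad) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            gx(ii, jj, c) += Mg(i + H * j, col);
          }
        }
      }
    }
  }
  return gx;
}

// y[h,w,co] = sum_{ki,kj,ci} x[h+ki-p, w+kj-p, ci] * w[ki,kj,ci,co] + b[co]
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch in conv forward");
  const int pad = k / 2;
  arma::cube xc(x.begin(), H, W, Cin, false);
  arma::mat wm(w.begin(), k * k * Cin, Cout, false);
  arma::mat y = im2col_same(xc, k, pad) * wm;
  arma::rowvec bv(b.begin(), Cout, false);
  y.each_row() += bv;
  NumericVector out(H * W * Cout);
  std::copy(y.begin(), y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// Gradient of the loss w.r.t. kernel and bias given input x and output grad gy.
// [[Rcpp::export]]
List cpp_conv_gradw(NumericVector x, NumericVector gy, int k) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], Cout = gd[2];
  const int pad = k / 2;
  arma::cube xc(x.begin(), H, W, Cin, false);
  arma::mat gm(gy.begin(), H * W, Cout, false);
  arma::mat gw = im2col_same(xc, k, pad).t() * gm;
  NumericVector gwv(k * k * Cin * Cout);
  std::copy(gw.begin(), gw.end(), gwv.begin());
  gwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  arma::rowvec gb = arma::sum(gm, 0);
  return List::create(_["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Gradient of the loss w.r.t. the conv input (the adjoint of cpp_conv_fwd).
// [[Rcpp::export]]
NumericVector cpp_conv_gradx(NumericVector gy, NumericVector w) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int H = gd[0], W = gd[1], Cout = gd[2];
  const int k = wd[0], Cin = wd[2];
  const int pad = k / 2;
  arma::mat gm(gy.begin(), H * W, Cout, false);
  arma::mat wm(w.begin(), k * k * Cin, Cout, false);
  arma::mat Mg = gm * wm.t();
  arma::cube gx = col2im_same(Mg, H, W, Cin, k, pad);
  NumericVector out(H * W * Cin);
  std::copy(gx.begin(), gx.end(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, Cin);
  return out;
}

// 2x2 max pooling (H, W even); records 1-based argmax indices for backprop.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = -1;
        double bv = -1e300;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int lin = (2 * i + di) + H * (2 * j + dj) + H * W * c;
            if (x[lin] > bv) { bv = x[lin]; best = lin; }
          }
        }
        const int o = i + Ho * j + Ho * Wo * c;
        y[o] = bv;
        idx[o] = best + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_back(NumericVector gy, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector gx(xdim[0] * xdim[1] * xdim[2]);
  for (int i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// 8-connected component labeling of a binary matrix (0 background).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (m(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + H * j0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (m(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// CRC-32 (PNG/zlib polynomial), for the 16-bit PNG chunk writer.
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[n] = c;
    }
    have = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
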