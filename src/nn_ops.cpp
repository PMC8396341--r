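// Dense numeric kernels for the encoder-decoder network: stride-1 'same'
// convolution via im2col, 2x2 max pooling, and 2x bilinear upsampling,
// each with its adjoint for backpropagation. Tensors are H x W x C cubes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a k x k stride-1 'same' convolution (zero padding).
// Column order: (dy, dx, cin) fastest to slowest matches the R-side
// weight layout w[(k*k*cin) x cout].
static mat im2col_same(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  mat cols(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        double* dst = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - p;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) dst[j * H + i] = 0.0;
            continue;
          }
          const double* src = xc.colptr(sj);
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - p;
            dst[j * H + i] = (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat cols = im2col_same(x, k);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices, p = (k - 1) / 2;
  mat dymat(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dymat.col(c) = vectorise(dy.slice(c));
  mat cols = im2col_same(x, k);
  mat dw = cols.t() * dymat;
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w.t();
  cube dx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    mat& dxc = dx.slice(c);
    for (int dxo = 0; dxo < k; ++dxo) {
      for (int dyo = 0; dyo < k; ++dyo) {
        const int col = c * k * k + dxo * k + dyo;
        const double* src = dcols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dxo - p;
          if (sj < 0 || sj >= W) continue;
          double* dst = dxc.colptr(sj);
          for (int i = 0; i < H; ++i) {
            const int si = i + dyo - p;
            if (si >= 0 && si < H) dst[si] += src[j * H + i];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::_["dx"] = dx, Rcpp::_["dw"] = dw,
                            Rcpp::_["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("maxpool2 requires even spatial dimensions");
  cube y(H / 2, W / 2, C);
  Rcpp::IntegerVector arg((R_xlen_t)(H / 2) * (W / 2) * C);
  R_xlen_t k = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double best = -datum::inf; int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        arg[k++] = c * H * W + bj * H + bi;  // linear index into x
      }
    }
  }
  return Rcpp::List::create(Rcpp::_["y"] = y, Rcpp::_["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::cube& dy, const Rcpp::IntegerVector& argmax,
                       int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double* src = dy.memptr();
  double* dst = dx.memptr();
  for (R_xlen_t k = 0; k < argmax.size(); ++k)
    dst[argmax[k]] += src[k];
  return dx;
}

// 2x bilinear upsampling, half-pixel centers (align_corners = FALSE).
static void up2_weights(int Hout, int Hin, ivec& i0, ivec& i1, vec& w1) {
  i0.set_size(Hout); i1.set_size(Hout); w1.set_size(Hout);
  for (int o = 0; o < Hout; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > Hin - 1) s = Hin - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, Hin - 1);
    i0[o] = lo; i1[o] = hi; w1[o] = s - lo;
  }
}

// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ivec r0, r1, c0, c1; vec wr, wc;
  up2_weights(2 * H, H, r0, r1, wr);
  up2_weights(2 * W, W, c0, c1, wc);
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      for (int i = 0; i < 2 * H; ++i) {
        double top = (1 - wc[j]) * xc(r0[i], c0[j]) + wc[j] * xc(r0[i], c1[j]);
        double bot = (1 - wc[j]) * xc(r1[i], c0[j]) + wc[j] * xc(r1[i], c1[j]);
        yc(i, j) = (1 - wr[i]) * top + wr[i] * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& dy) {
  const int Hout = dy.n_rows, Wout = dy.n_cols, C = dy.n_slices;
  const int H = Hout / 2, W = Wout / 2;
  ivec r0, r1, c0, c1; vec wr, wc;
  up2_weights(Hout, H, r0, r1, wr);
  up2_weights(Wout, W, c0, c1, wc);
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& gc = dy.slice(c);
    mat& dc = dx.slice(c);
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        double g = gc(i, j);
        dc(r0[i], c0[j]) += (1 - wr[i]) * (1 - wc[j]) * g;
        dc(r0[i], c1[j]) += (1 - wr[i]) * wc[j] * g;
        dc(r1[i], c0[j]) += wr[i] * (1 - wc[j]) * g;
        dc(r1[i], c1[j]) += wr[i] * wc[j] * g;
      }
    }
  }
  return dx;
}
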