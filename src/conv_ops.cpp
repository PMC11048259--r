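// Minimal conv-net primitives: 2-D convolution ("same" padding, stride 1)
// via im2col + GEMM, and 2x2 max pooling with argmax bookkeeping.
// Tensors are R arrays in (h, w, channels, n) layout (column-major).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col_same(const double* x, int h, int w, int cin,
                                    int k) {
  // rows: output positions (i + h*j), cols: k*k*cin patch entries
  const int pad_top = (k - 1) / 2;
  const int pad_left = (k - 1) / 2;
  arma::mat M(h * w, k * k * cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    const double* plane = x + (std::size_t)h * w * ch;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * ch);
        for (int j = 0; j < w; ++j) {
          const int sj = j - pad_left + kj;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            const int si = i - pad_top + ki;
            if (si < 0 || si >= h) continue;
            M(i + h * j, col) = plane[si + h * sj];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int h = xd[0], wid = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], cout = wd[3];
  if (wd[1] != k || wd[2] != cin) stop("weight dims inconsistent with input");
  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * cin, cout, false);
  NumericVector out((R_xlen_t)h * wid * cout * n);
  out.attr("dim") = IntegerVector::create(h, wid, cout, n);
  arma::rowvec bv(const_cast<double*>(b.begin()), cout, false);
  for (int im = 0; im < n; ++im) {
    const double* xi = x.begin() + (std::size_t)h * wid * cin * im;
    arma::mat M = im2col_same(xi, h, wid, cin, k);
    arma::mat Y = M * Wmat;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(),
              out.begin() + (std::size_t)h * wid * cout * im);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int h = xd[0], wid = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], cout = wd[3];
  const int pad_top = (k - 1) / 2, pad_left = (k - 1) / 2;
  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * cin, cout, false);
  NumericVector dx((R_xlen_t)h * wid * cin * n);
  dx.attr("dim") = IntegerVector::create(h, wid, cin, n);
  arma::mat dW(k * k * cin, cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  for (int im = 0; im < n; ++im) {
    const double* xi = x.begin() + (std::size_t)h * wid * cin * im;
    arma::mat M = im2col_same(xi, h, wid, cin, k);
    arma::mat dY(const_cast<double*>(dy.begin()) +
                     (std::size_t)h * wid * cout * im,
                 h * wid, cout, false);
    dW += M.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = dY * Wmat.t();  // (h*w) x (k*k*cin)
    double* dxi = dx.begin() + (std::size_t)h * wid * cin * im;
    for (int ch = 0; ch < cin; ++ch) {
      double* plane = dxi + (std::size_t)h * wid * ch;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int col = ki + k * (kj + k * ch);
          for (int j = 0; j < wid; ++j) {
            const int sj = j - pad_left + kj;
            if (sj < 0 || sj >= wid) continue;
            for (int i = 0; i < h; ++i) {
              const int si = i - pad_top + ki;
              if (si < 0 || si >= h) continue;
              plane[si + h * sj] += dM(i + h * j, col);
            }
          }
        }
      }
    }
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int h2 = h / 2, w2 = w / 2;
  if (h2 < 1 || w2 < 1) stop("input too small to pool");
  NumericVector y((R_xlen_t)h2 * w2 * c * n);
  y.attr("dim") = IntegerVector::create(h2, w2, c, n);
  IntegerVector idx((R_xlen_t)h2 * w2 * c * n);  // 0-based index in input plane
  idx.attr("dim") = IntegerVector::create(h2, w2, c, n);
  for (int im = 0; im < n; ++im) {
    for (int ch = 0; ch < c; ++ch) {
      const double* plane = x.begin() + (std::size_t)h * w * (ch + c * im);
      double* yp = y.begin() + (std::size_t)h2 * w2 * (ch + c * im);
      int* ip = idx.begin() + (std::size_t)h2 * w2 * (ch + c * im);
      for (int j = 0; j < w2; ++j) {
        for (int i = 0; i < h2; ++i) {
          int best = (2 * i) + h * (2 * j);
          double bv = plane[best];
          const int cand[3] = {(2 * i + 1) + h * (2 * j),
                               (2 * i) + h * (2 * j + 1),
                               (2 * i + 1) + h * (2 * j + 1)};
          for (int q = 0; q < 3; ++q) {
            if (plane[cand[q]] > bv) {
              bv = plane[cand[q]];
              best = cand[q];
            }
          }
          yp[i + h2 * j] = bv;
          ip[i + h2 * j] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector dy, int h,
                                   int w) {
  IntegerVector yd = dy.attr("dim");
  const int h2 = yd[0], w2 = yd[1], c = yd[2], n = yd[3];
  NumericVector dx((R_xlen_t)h * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  for (int im = 0; im < n; ++im) {
    for (int ch = 0; ch < c; ++ch) {
      const std::size_t off2 = (std::size_t)h2 * w2 * (ch + c * im);
      double* plane = dx.begin() + (std::size_t)h * w * (ch + c * im);
      for (std::size_t q = 0; q < (std::size_t)h2 * w2; ++q) {
        plane[idx[off2 + q]] += dy[off2 + q];
      }
    }
  }
  return dx;
}
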