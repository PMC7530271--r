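// Batched kernels for the small convolutional embedding: 3x3 same-padding
// convolution via im2col + GEMM, batch normalization (batch statistics, no
// affine) fused with ReLU, and 2x2 max pooling.  Layouts:
//   activations  : (H*W*C) x B, column-major per image, flat index
//                  h + H*w + H*W*c  (h fastest, matching R arrays)
//   conv weights : (9*C) x F, patch index kk + 9*c with
//                  kk = (dh+1) + 3*(dw+1), dh/dw in {-1,0,1}
// All backward passes are exact gradients of the forward computation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3x3(const arma::mat& X, int H, int W, int C) {
  const int B = X.n_cols, HW = H * W;
  arma::mat K(9 * C, (arma::uword)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    for (int c = 0; c < C; ++c) {
      const double* xc = xb + (arma::uword)HW * c;
      for (int dw = -1; dw <= 1; ++dw) {
        for (int dh = -1; dh <= 1; ++dh) {
          const int kk = (dh + 1) + 3 * (dw + 1);
          const int row = kk + 9 * c;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw;
            if (ws < 0 || ws >= W) continue;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            double* kcol = K.memptr();
            for (int h = h0; h < h1; ++h) {
              const arma::uword col = (arma::uword)HW * b + h + H * w;
              kcol[row + K.n_rows * col] = xc[(h + dh) + H * ws];
            }
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export]]
List cpp_conv3x3_forward(const arma::mat& X, const arma::mat& Wt,
                         const arma::vec& bias, int H, int W, int C) {
  const int B = X.n_cols, HW = H * W, F = Wt.n_cols;
  arma::mat K = im2col3x3(X, H, W, C);
  arma::mat Y = Wt.t() * K;              // F x (HW*B)
  Y.each_col() += bias;
  arma::mat out((arma::uword)HW * F, B);
  for (int b = 0; b < B; ++b) {
    arma::mat block = Y.cols((arma::uword)HW * b, (arma::uword)HW * (b + 1) - 1);
    out.col(b) = arma::vectorise(block.t());   // p fastest, then f
  }
  return List::create(_["out"] = out, _["cols"] = K);
}

// [[Rcpp::export]]
List cpp_conv3x3_backward(const arma::mat& dOut, const arma::mat& K,
                          const arma::mat& Wt, int H, int W, int C, int F) {
  const int B = dOut.n_cols, HW = H * W;
  arma::mat dY(F, (arma::uword)HW * B);
  for (int b = 0; b < B; ++b) {
    arma::mat block(dOut.colptr(b), HW, F);  // copy view: HW x F
    dY.cols((arma::uword)HW * b, (arma::uword)HW * (b + 1) - 1) = block.t();
  }
  arma::mat dWt = (dY * K.t()).t();          // (9C) x F
  arma::vec db = arma::sum(dY, 1);
  arma::mat dK = Wt * dY;                    // (9C) x (HW*B), col2im follows
  arma::mat dX((arma::uword)HW * C, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* xb = dX.colptr(b);
    for (int c = 0; c < C; ++c) {
      double* xc = xb + (arma::uword)HW * c;
      for (int dw = -1; dw <= 1; ++dw) {
        for (int dh = -1; dh <= 1; ++dh) {
          const int kk = (dh + 1) + 3 * (dw + 1);
          const int row = kk + 9 * c;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw;
            if (ws < 0 || ws >= W) continue;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const double* kcol = dK.memptr();
            for (int h = h0; h < h1; ++h) {
              const arma::uword col = (arma::uword)HW * b + h + H * w;
              xc[(h + dh) + H * ws] += kcol[row + dK.n_rows * col];
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_bn_relu_forward(const arma::mat& X, int C, double eps) {
  const int B = X.n_cols;
  const int HW = X.n_rows / C;
  arma::mat ynorm(X.n_rows, B), out(X.n_rows, B);
  arma::vec invstd(C);
  const double n = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    arma::mat slice = X.rows((arma::uword)HW * c, (arma::uword)HW * (c + 1) - 1);
    const double mu = arma::accu(slice) / n;
    slice -= mu;
    const double var = arma::accu(arma::square(slice)) / n;
    const double inv = 1.0 / std::sqrt(var + eps);
    invstd(c) = inv;
    slice *= inv;
    ynorm.rows((arma::uword)HW * c, (arma::uword)HW * (c + 1) - 1) = slice;
    slice.transform([](double v) { return v > 0 ? v : 0.0; });
    out.rows((arma::uword)HW * c, (arma::uword)HW * (c + 1) - 1) = slice;
  }
  return List::create(_["out"] = out, _["ynorm"] = ynorm,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
arma::mat cpp_bn_relu_backward(const arma::mat& dOut, const arma::mat& ynorm,
                               const arma::vec& invstd, int C) {
  const int B = dOut.n_cols;
  const int HW = dOut.n_rows / C;
  arma::mat dX(dOut.n_rows, B);
  const double n = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    const arma::uword r0 = (arma::uword)HW * c, r1 = (arma::uword)HW * (c + 1) - 1;
    arma::mat yh = ynorm.rows(r0, r1);
    arma::mat mask = arma::conv_to<arma::mat>::from(yh > 0);
    arma::mat dyr = dOut.rows(r0, r1) % mask;      // through ReLU
    const double mean_dy = arma::accu(dyr) / n;
    const double mean_dyyh = arma::accu(dyr % yh) / n;
    dX.rows(r0, r1) = invstd(c) * (dyr - mean_dy - yh * mean_dyyh);
  }
  return dX;
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::mat& X, int H, int W, int C) {
  const int B = X.n_cols, Ho = H / 2, Wo = W / 2;
  const int HWo = Ho * Wo;
  arma::mat out((arma::uword)HWo * C, B);
  arma::umat idx((arma::uword)HWo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    double* ob = out.colptr(b);
    arma::uword* ib = idx.colptr(b);
    for (int c = 0; c < C; ++c) {
      const arma::uword off_in = (arma::uword)H * W * c;
      const arma::uword off_out = (arma::uword)HWo * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          arma::uword best = off_in + (2 * ho) + H * (2 * wo);
          double bv = xb[best];
          const arma::uword cand[3] = {
            off_in + (2 * ho + 1) + H * (2 * wo),
            off_in + (2 * ho) + H * (2 * wo + 1),
            off_in + (2 * ho + 1) + H * (2 * wo + 1)};
          for (int k = 0; k < 3; ++k) {
            if (xb[cand[k]] > bv) { bv = xb[cand[k]]; best = cand[k]; }
          }
          ob[off_out + ho + Ho * wo] = bv;
          ib[off_out + ho + Ho * wo] = best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_backward(const arma::mat& dOut, const arma::umat& idx,
                                int in_rows) {
  const int B = dOut.n_cols;
  arma::mat dX(in_rows, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* db = dOut.colptr(b);
    const arma::uword* ib = idx.colptr(b);
    double* xb = dX.colptr(b);
    for (arma::uword r = 0; r < dOut.n_rows; ++r) xb[ib[r]] += db[r];
  }
  return dX;
}
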