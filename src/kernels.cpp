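// Performance kernels for the patch CNN.
//
// Feature-map batches are R matrices of shape (H*W*B) x C: spatial index
// fastest (column-major within a sample), then sample, one column per
// channel. im2col produces (H*W*B) x (C*k*k) with the channel fastest
// within each kernel-offset block and offsets ordered row-offset fastest;
// this matches aperm(weights, c(3,1,2,4)) on the R side so a convolution
// is a single BLAS product. Pooling uses ceil-mode windows clipped at the
// border (averages divide by the clipped window size).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& A, int H, int W, int B,
                         int k, int pad) {
  const int C = A.ncol();
  const int P = H * W * B;
  NumericMatrix Cols(P, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* src = &A(0, c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = &Cols(0, (di + dj * k) * C + c);
        for (int b = 0; b < B; ++b) {
          const int boff = b * H * W;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            double* d = dst + boff + j * H;
            if (jj < 0 || jj >= W) continue;     // Cols initialized to 0
            const double* s = src + boff + jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + di - pad;
              if (ii >= 0 && ii < H) d[i] = s[ii];
            }
          }
        }
      }
    }
  }
  return Cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dCols, int H, int W, int B,
                         int C, int k, int pad) {
  const int P = H * W * B;
  NumericMatrix dA(P, C);
  for (int c = 0; c < C; ++c) {
    double* dst = &dA(0, c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = &dCols(0, (di + dj * k) * C + c);
        for (int b = 0; b < B; ++b) {
          const int boff = b * H * W;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            const double* s = src + boff + j * H;
            double* d = dst + boff + jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + di - pad;
              if (ii >= 0 && ii < H) d[ii] += s[i];
            }
          }
        }
      }
    }
  }
  return dA;
}

static inline int pool_out(int H, int k, int s) {
  return (int)std::ceil((double)(H - k) / s) + 1;
}

// [[Rcpp::export]]
List cpp_pool_max_forward(const NumericMatrix& A, int H, int W, int B,
                          int k, int s) {
  const int C = A.ncol();
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  const int P = Ho * Wo * B;
  NumericMatrix Out(P, C);
  IntegerMatrix Arg(P, C);     // 0-based input row index of the max
  for (int c = 0; c < C; ++c) {
    const double* src = &A(0, c);
    for (int b = 0; b < B; ++b) {
      const int bo_in = b * H * W, bo_out = b * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj) {
        const int j0 = oj * s, j1 = std::min(j0 + k, W);
        for (int oi = 0; oi < Ho; ++oi) {
          const int i0 = oi * s, i1 = std::min(i0 + k, H);
          double m = -INFINITY; int am = -1;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) {
              const int r = bo_in + j * H + i;
              if (src[r] > m) { m = src[r]; am = r; }
            }
          Out(bo_out + oj * Ho + oi, c) = m;
          Arg(bo_out + oj * Ho + oi, c) = am;
        }
      }
    }
  }
  return List::create(_["out"] = Out, _["argmax"] = Arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_max_backward(const NumericMatrix& dOut,
                                    const IntegerMatrix& Arg,
                                    int H, int W, int B) {
  const int C = dOut.ncol();
  NumericMatrix dA(H * W * B, C);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < dOut.nrow(); ++p)
      dA(Arg(p, c), c) += dOut(p, c);
  return dA;
}

// [[Rcpp::export]]
List cpp_pool_avg_forward(const NumericMatrix& A, int H, int W, int B,
                          int k, int s) {
  const int C = A.ncol();
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  const int P = Ho * Wo * B;
  NumericMatrix Out(P, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &A(0, c);
    for (int b = 0; b < B; ++b) {
      const int bo_in = b * H * W, bo_out = b * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj) {
        const int j0 = oj * s, j1 = std::min(j0 + k, W);
        for (int oi = 0; oi < Ho; ++oi) {
          const int i0 = oi * s, i1 = std::min(i0 + k, H);
          double acc = 0.0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              acc += src[bo_in + j * H + i];
          Out(bo_out + oj * Ho + oi, c) = acc / ((i1 - i0) * (j1 - j0));
        }
      }
    }
  }
  return List::create(_["out"] = Out);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_avg_backward(const NumericMatrix& dOut,
                                    int H, int W, int B, int k, int s) {
  const int C = dOut.ncol();
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  NumericMatrix dA(H * W * B, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const int bo_in = b * H * W, bo_out = b * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj) {
        const int j0 = oj * s, j1 = std::min(j0 + k, W);
        for (int oi = 0; oi < Ho; ++oi) {
          const int i0 = oi * s, i1 = std::min(i0 + k, H);
          const double g = dOut(bo_out + oj * Ho + oi, c) /
                           ((i1 - i0) * (j1 - j0));
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              dA(bo_in + j * H + i, c) += g;
        }
      }
    }
  }
  return dA;
}
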