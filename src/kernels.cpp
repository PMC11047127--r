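#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Dense 3D tensor kernels. All tensors are column-major R arrays with axis
// order (batch, H, W, D, C); linear index b + B*(i + H*(j + W*(k + D*c))).
// Convolutions use stride 1 and "same" zero padding with odd cubic kernels.

static inline R_xlen_t idx5(int b, int i, int j, int k, int c,
                            int B, int H, int W, int D) {
  return b + (R_xlen_t)B * (i + (R_xlen_t)H * (j + (R_xlen_t)W * (k + (R_xlen_t)D * c)));
}

// The convolution is evaluated as a sum of shifted copies: for each kernel
// offset (a,q,c) the contribution w[a,q,c,ci,co] * x[shifted] is added over
// the valid output range. The (batch, H) axes are contiguous in memory, so
// for every (j,k) slice the inner loop is a branch-free saxpy over
// B * n_valid_rows elements.

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias) {
  const int B = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], Ci = xdim[4];
  const int K = wdim[0], Co = wdim[4];
  const int p = (K - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)B * H * W * D;
  NumericVector y(plane * Co);
  const double* xp0 = x.begin();
  double* yp0 = y.begin();
  const double* wp = w.begin();
  for (int co = 0; co < Co; ++co) {
    double* yco = yp0 + plane * co;
    const double b0 = bias[co];
    for (R_xlen_t t = 0; t < plane; ++t) yco[t] = b0;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = xp0 + plane * ci;
      for (int c = 0; c < K; ++c) {
        const int dk = c - p;
        const int k0 = dk < 0 ? -dk : 0, k1 = dk > 0 ? D - dk : D;
        for (int q = 0; q < K; ++q) {
          const int dj = q - p;
          const int j0 = dj < 0 ? -dj : 0, j1 = dj > 0 ? W - dj : W;
          for (int a = 0; a < K; ++a) {
            const double wv = wp[a + (R_xlen_t)K * (q + (R_xlen_t)K * (c + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)))];
            if (wv == 0.0) continue;
            const int di = a - p;
            const int i0 = di < 0 ? -di : 0, i1 = di > 0 ? H - di : H;
            const R_xlen_t nrun = (R_xlen_t)B * (i1 - i0);
            if (nrun <= 0) continue;
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                double* yp = yco + idx5(0, i0, j, k, 0, B, H, W, D);
                const double* xp = xci + idx5(0, i0 + di, j + dj, k + dk, 0, B, H, W, D);
                for (R_xlen_t t = 0; t < nrun; ++t) yp[t] += wv * xp[t];
              }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, H, W, D, Co);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy) {
  const int B = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], Ci = xdim[4];
  const int K = wdim[0], Co = wdim[4];
  const int p = (K - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)B * H * W * D;
  NumericVector dx(plane * Ci);
  NumericVector dw(w.size());
  NumericVector db(Co);
  const double* xp0 = x.begin();
  const double* gp0 = dy.begin();
  const double* wp = w.begin();
  double* dxp0 = dx.begin();
  double* dwp = dw.begin();
  for (int co = 0; co < Co; ++co) {
    const double* gco = gp0 + plane * co;
    double acc_b = 0.0;
    for (R_xlen_t t = 0; t < plane; ++t) acc_b += gco[t];
    db[co] = acc_b;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = xp0 + plane * ci;
      double* dxci = dxp0 + plane * ci;
      for (int c = 0; c < K; ++c) {
        const int dk = c - p;
        const int k0 = dk < 0 ? -dk : 0, k1 = dk > 0 ? D - dk : D;
        for (int q = 0; q < K; ++q) {
          const int dj = q - p;
          const int j0 = dj < 0 ? -dj : 0, j1 = dj > 0 ? W - dj : W;
          for (int a = 0; a < K; ++a) {
            const R_xlen_t wi = a + (R_xlen_t)K * (q + (R_xlen_t)K * (c + (R_xlen_t)K * (ci + (R_xlen_t)Ci * co)));
            const double wv = wp[wi];
            const int di = a - p;
            const int i0 = di < 0 ? -di : 0, i1 = di > 0 ? H - di : H;
            const R_xlen_t nrun = (R_xlen_t)B * (i1 - i0);
            if (nrun <= 0) continue;
            double acc_w = 0.0;
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                const double* gp = gco + idx5(0, i0, j, k, 0, B, H, W, D);
                const double* xp = xci + idx5(0, i0 + di, j + dj, k + dk, 0, B, H, W, D);
                double* dxp = dxci + idx5(0, i0 + di, j + dj, k + dk, 0, B, H, W, D);
                for (R_xlen_t t = 0; t < nrun; ++t) {
                  const double g = gp[t];
                  dxp[t] += wv * g;
                  acc_w += xp[t] * g;
                }
              }
            dwp[wi] += acc_w;
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(B, H, W, D, Ci);
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transpose convolution, kernel 2, stride 2: doubles every spatial dim.
// y[b, 2i+a, 2j+q, 2k+c, co] = bias[co] + sum_ci x[b,i,j,k,ci] * w[a,q,c,ci,co]
// [[Rcpp::export]]
NumericVector upconv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                               NumericVector w, NumericVector bias) {
  const int B = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], Ci = xdim[4];
  const int Co = (int)(w.size() / (8 * Ci));
  const int H2 = 2 * H, W2 = 2 * W, D2 = 2 * D;
  NumericVector y((R_xlen_t)B * H2 * W2 * D2 * Co);
  for (int co = 0; co < Co; ++co) {
    const double b0 = bias[co];
    for (R_xlen_t t = 0; t < (R_xlen_t)B * H2 * W2 * D2; ++t)
      y[t + (R_xlen_t)B * H2 * W2 * D2 * co] = b0;
  }
  for (int co = 0; co < Co; ++co)
    for (int k = 0; k < D; ++k)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          for (int b = 0; b < B; ++b)
            for (int c = 0; c < 2; ++c)
              for (int q = 0; q < 2; ++q)
                for (int a = 0; a < 2; ++a) {
                  double acc = 0.0;
                  for (int ci = 0; ci < Ci; ++ci)
                    acc += x[idx5(b, i, j, k, ci, B, H, W, D)] *
                           w[a + 2 * (q + 2 * (c + 2 * (ci + (R_xlen_t)Ci * co)))];
                  y[idx5(b, 2 * i + a, 2 * j + q, 2 * k + c, co, B, H2, W2, D2)] += acc;
                }
  y.attr("dim") = IntegerVector::create(B, H2, W2, D2, Co);
  return y;
}

// [[Rcpp::export]]
List upconv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                      NumericVector w, NumericVector dy) {
  const int B = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], Ci = xdim[4];
  const int Co = (int)(w.size() / (8 * Ci));
  const int H2 = 2 * H, W2 = 2 * W, D2 = 2 * D;
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Co);
  for (int co = 0; co < Co; ++co)
    for (int k = 0; k < D; ++k)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          for (int b = 0; b < B; ++b)
            for (int c = 0; c < 2; ++c)
              for (int q = 0; q < 2; ++q)
                for (int a = 0; a < 2; ++a) {
                  const double g = dy[idx5(b, 2 * i + a, 2 * j + q, 2 * k + c, co, B, H2, W2, D2)];
                  for (int ci = 0; ci < Ci; ++ci) {
                    const R_xlen_t xi = idx5(b, i, j, k, ci, B, H, W, D);
                    const R_xlen_t wi = a + 2 * (q + 2 * (c + 2 * (ci + (R_xlen_t)Ci * co)));
                    dx[xi] += g * w[wi];
                    dw[wi] += g * x[xi];
                  }
                }
  for (int co = 0; co < Co; ++co)
    for (R_xlen_t t = 0; t < (R_xlen_t)B * H2 * W2 * D2; ++t)
      db[co] += dy[t + (R_xlen_t)B * H2 * W2 * D2 * co];
  dx.attr("dim") = xdim;
  IntegerVector wd = IntegerVector::create(2, 2, 2, Ci, Co);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, 3x3x3 kernel, stride 2, padding 1 (out-of-range treated as -Inf).
// Returns pooled values and 1-based argmax linear indices into x for backward.
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int B = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], C = xdim[4];
  const int Ho = (H - 1) / 2 + 1, Wo = (W - 1) / 2 + 1, Do = (D - 1) / 2 + 1;
  NumericVector y((R_xlen_t)B * Ho * Wo * Do * C);
  NumericVector arg(y.size());
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < Do; ++k)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          for (int b = 0; b < B; ++b) {
            double best = -DBL_MAX; R_xlen_t bi = -1;
            for (int dz = -1; dz <= 1; ++dz) {
              const int kz = 2 * k + dz; if (kz < 0 || kz >= D) continue;
              for (int dyq = -1; dyq <= 1; ++dyq) {
                const int jy = 2 * j + dyq; if (jy < 0 || jy >= W) continue;
                for (int dxp = -1; dxp <= 1; ++dxp) {
                  const int ix = 2 * i + dxp; if (ix < 0 || ix >= H) continue;
                  const R_xlen_t xi = idx5(b, ix, jy, kz, c, B, H, W, D);
                  if (x[xi] > best) { best = x[xi]; bi = xi; }
                }
              }
            }
            const R_xlen_t yi = idx5(b, i, j, k, c, B, Ho, Wo, Do);
            y[yi] = best;
            arg[yi] = (double)(bi + 1);
          }
  y.attr("dim") = IntegerVector::create(B, Ho, Wo, Do, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector argmax, NumericVector dy,
                                IntegerVector xdim) {
  R_xlen_t n = 1; for (int a = 0; a < 5; ++a) n *= xdim[a];
  NumericVector dx(n);
  for (R_xlen_t t = 0; t < dy.size(); ++t)
    dx[(R_xlen_t)argmax[t] - 1] += dy[t];
  dx.attr("dim") = xdim;
  return dx;
}

// For each row of A (n x 3 voxel coordinates), the minimum Euclidean distance
// to any row of Bm, with coordinates scaled by per-axis spacing (mm).
// [[Rcpp::export]]
NumericVector nn_min_dists_cpp(NumericMatrix A, NumericMatrix Bm,
                               NumericVector spacing) {
  const int n = A.nrow(), m = Bm.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = DBL_MAX;
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - Bm(j, 0) * sx;
      const double dy = ay - Bm(j, 1) * sy;
      const double dz = az - Bm(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
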