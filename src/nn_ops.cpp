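// Hot numeric kernels for the multiscale CNN: same-padding convolution via
// im2col/col2im and ceil-mode max-pooling. Activations are stored as
// (H*W*B) x C matrices, row index = i + H*j + H*W*b (0-based, column-major
// within each image), matching R's native array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X column index = o + k2*c, o = (di+r) + k*(dj+r): kernel offset fastest.
static arma::mat im2col_same(const arma::mat& A, int H, int W, int B, int k) {
  const int HW = H * W, k2 = k * k, C = A.n_cols, r = (k - 1) / 2;
  arma::mat X(static_cast<size_t>(HW) * B, static_cast<size_t>(k2) * C,
              arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int o = 0; o < k2; ++o) {
      const int di = o % k - r, dj = o / k - r;
      double* dst = X.colptr(static_cast<size_t>(c) * k2 + o);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      for (int b = 0; b < B; ++b) {
        const double* s = src + static_cast<size_t>(b) * HW;
        double* d = dst + static_cast<size_t>(b) * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const double* scol = s + static_cast<size_t>(jj) * H + di;
          double* dcol = d + static_cast<size_t>(j) * H;
          for (int i = i0; i < i1; ++i) dcol[i] = scol[i];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat nn_conv_fwd(const arma::mat& A, const arma::mat& Wt,
                      const arma::vec& b, int H, int W, int B, int k,
                      bool relu = false) {
  arma::mat Y = im2col_same(A, H, W, B, k) * Wt;
  Y.each_row() += b.t();
  if (relu) Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

// [[Rcpp::export]]
List nn_conv_bwd(const arma::mat& A, const arma::mat& dY, const arma::mat& Wt,
                 int H, int W, int B, int k, bool need_da = true) {
  arma::mat X = im2col_same(A, H, W, B, k);
  arma::mat dW = X.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  if (!need_da)
    return List::create(_["dA"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  arma::mat dXcol = dY * Wt.t();
  const int HW = H * W, k2 = k * k, C = A.n_cols, r = (k - 1) / 2;
  arma::mat dA(static_cast<size_t>(HW) * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dA.colptr(c);
    for (int o = 0; o < k2; ++o) {
      const int di = o % k - r, dj = o / k - r;
      const double* src = dXcol.colptr(static_cast<size_t>(c) * k2 + o);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      for (int b2 = 0; b2 < B; ++b2) {
        const double* s = src + static_cast<size_t>(b2) * HW;
        double* d = dst + static_cast<size_t>(b2) * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          double* dcol = d + static_cast<size_t>(jj) * H + di;
          const double* scol = s + static_cast<size_t>(j) * H;
          for (int i = i0; i < i1; ++i) dcol[i] += scol[i];
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// Ceil-mode output sizing: out = ceil((n - k)/s) + 1; trailing windows are
// truncated at the image edge. Ties go to the first element scanned
// (smallest i, then smallest j) for determinism.
// [[Rcpp::export]]
List nn_maxpool_fwd(const arma::mat& A, int H, int W, int B, int k, int s,
                    bool ceil_mode) {
  const int C = A.n_cols, HW = H * W;
  auto osz = [&](int n) {
    const double q = static_cast<double>(n - k) / s;
    return (ceil_mode ? static_cast<int>(std::ceil(q))
                      : static_cast<int>(std::floor(q))) + 1;
  };
  const int Ho = osz(H), Wo = osz(W), HWo = Ho * Wo;
  arma::mat Y(static_cast<size_t>(HWo) * B, C);
  arma::imat idx(static_cast<size_t>(HWo) * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* y = Y.colptr(c);
    arma::sword* ix = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* s2 = src + static_cast<size_t>(b) * HW;
      for (int jo = 0; jo < Wo; ++jo) {
        const int j0 = jo * s, j1 = std::min(j0 + k, W);
        for (int io = 0; io < Ho; ++io) {
          const int i0 = io * s, i1 = std::min(i0 + k, H);
          double best = -INFINITY;
          int bi = i0 + H * j0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) {
              const double v = s2[static_cast<size_t>(j) * H + i];
              if (v > best) { best = v; bi = j * H + i; }
            }
          const size_t orow = static_cast<size_t>(b) * HWo + jo * Ho + io;
          y[orow] = best;
          ix[orow] = bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx, _["Ho"] = Ho, _["Wo"] = Wo);
}

// Fused conv -> bias -> ReLU -> ceil-mode max-pool. Only the pooled
// activations and argmax indices surface to R; the full-resolution
// convolution output stays in this translation unit.
// [[Rcpp::export]]
List nn_conv_pool_fwd(const arma::mat& A, const arma::mat& Wt,
                      const arma::vec& b, int H, int W, int B, int k,
                      int pk, int ps, bool ceil_mode) {
  arma::mat Z = im2col_same(A, H, W, B, k) * Wt;
  Z.each_row() += b.t();
  Z.for_each([](double& v) { if (v < 0) v = 0; });
  const int C = Z.n_cols, HW = H * W;
  auto osz = [&](int n) {
    const double q = static_cast<double>(n - pk) / ps;
    return (ceil_mode ? static_cast<int>(std::ceil(q))
                      : static_cast<int>(std::floor(q))) + 1;
  };
  const int Ho = osz(H), Wo = osz(W), HWo = Ho * Wo;
  arma::mat Y(static_cast<size_t>(HWo) * B, C);
  arma::imat idx(static_cast<size_t>(HWo) * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = Z.colptr(c);
    double* y = Y.colptr(c);
    arma::sword* ix = idx.colptr(c);
    for (int bb = 0; bb < B; ++bb) {
      const double* s2 = src + static_cast<size_t>(bb) * HW;
      for (int jo = 0; jo < Wo; ++jo) {
        const int j0 = jo * ps, j1 = std::min(j0 + pk, W);
        for (int io = 0; io < Ho; ++io) {
          const int i0 = io * ps, i1 = std::min(i0 + pk, H);
          double best = -INFINITY;
          int bi = i0 + H * j0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) {
              const double v = s2[static_cast<size_t>(j) * H + i];
              if (v > best) { best = v; bi = j * H + i; }
            }
          const size_t orow = static_cast<size_t>(bb) * HWo + jo * Ho + io;
          y[orow] = best;
          ix[orow] = bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx, _["Ho"] = Ho, _["Wo"] = Wo);
}

// Fused backward of the conv->ReLU->pool stage. `dP` is the gradient at
// the pooled output, `Ypool` the cached pooled activations (zero iff the
// ReLU clipped the winning element, which recovers the ReLU mask).
// [[Rcpp::export]]
List nn_conv_pool_bwd(const arma::mat& A, const arma::mat& dP,
                      const arma::mat& Ypool, const arma::imat& idx,
                      const arma::mat& Wt, int H, int W, int B, int k,
                      bool need_da = true) {
  const int C = dP.n_cols, HW = H * W;
  const int HWo = dP.n_rows / B;
  arma::mat dZ(static_cast<size_t>(HW) * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dP.colptr(c);
    const double* yp = Ypool.colptr(c);
    const arma::sword* ix = idx.colptr(c);
    double* dz = dZ.colptr(c);
    for (int bb = 0; bb < B; ++bb)
      for (int o = 0; o < HWo; ++o) {
        const size_t orow = static_cast<size_t>(bb) * HWo + o;
        if (yp[orow] > 0)
          dz[static_cast<size_t>(bb) * HW + ix[orow]] += dy[orow];
      }
  }
  arma::mat X = im2col_same(A, H, W, B, k);
  arma::mat dW = X.t() * dZ;
  arma::vec db = arma::sum(dZ, 0).t();
  if (!need_da)
    return List::create(_["dA"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  arma::mat dXcol = dZ * Wt.t();
  const int k2 = k * k, r = (k - 1) / 2;
  arma::mat dA(static_cast<size_t>(HW) * B, A.n_cols, arma::fill::zeros);
  for (int c = 0; c < static_cast<int>(A.n_cols); ++c) {
    double* dst = dA.colptr(c);
    for (int o = 0; o < k2; ++o) {
      const int di = o % k - r, dj = o / k - r;
      const double* src = dXcol.colptr(static_cast<size_t>(c) * k2 + o);
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      for (int b2 = 0; b2 < B; ++b2) {
        const double* s = src + static_cast<size_t>(b2) * HW;
        double* d = dst + static_cast<size_t>(b2) * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          double* dcol = d + static_cast<size_t>(jj) * H + di;
          const double* scol = s + static_cast<size_t>(j) * H;
          for (int i = i0; i < i1; ++i) dcol[i] += scol[i];
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
arma::mat nn_maxpool_bwd(const arma::mat& dY, const arma::imat& idx, int H,
                         int W, int B) {
  const int C = dY.n_cols, HW = H * W;
  const int HWo = dY.n_rows / B;
  arma::mat dA(static_cast<size_t>(HW) * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const arma::sword* ix = idx.colptr(c);
    double* da = dA.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int o = 0; o < HWo; ++o) {
        const size_t orow = static_cast<size_t>(b) * HWo + o;
        da[static_cast<size_t>(b) * HW + ix[orow]] += dy[orow];
      }
  }
  return dA;
}
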