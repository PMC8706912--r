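// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::umat;
using arma::uvec;
using arma::uword;

// Convolution layer (run as correlation) over a batch in the engine's
// internal layout: activations are (positions * B) x channels matrices,
// position fastest then sample. gidx (npos x fs) holds 0-based padded-plane
// indices of each patch element per output position; pad_pos embeds the
// unpadded plane into the padded one. The product with the (fs*C x K)
// filter bank is accumulated as one gemm per patch offset, so only the
// padded input needs to be kept for the backward pass.

static mat gather_offset(const mat& Xpad, const arma::imat& gidx, int f,
                         int plane, int B) {
  const int npos = gidx.n_rows;
  const int C = Xpad.n_cols;
  mat G(static_cast<uword>(npos) * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = Xpad.colptr(c);
    double* dst = G.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* srcb = src + static_cast<size_t>(b) * plane;
      double* dstb = dst + static_cast<size_t>(b) * npos;
      for (int q = 0; q < npos; ++q) dstb[q] = srcb[gidx(q, f)];
    }
  }
  return G;
}

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::mat& X, const arma::mat& W,
                  const arma::vec& bias, const arma::imat& gidx,
                  const arma::ivec& pad_pos, int plane, int B) {
  const int npin = pad_pos.n_elem;
  const int C = X.n_cols;
  const int fs = gidx.n_cols;
  const int npos = gidx.n_rows;
  const int K = W.n_cols;
  mat Xpad(static_cast<uword>(plane) * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = Xpad.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* srcb = src + static_cast<size_t>(b) * npin;
      double* dstb = dst + static_cast<size_t>(b) * plane;
      for (int q = 0; q < npin; ++q) dstb[pad_pos(q)] = srcb[q];
    }
  }
  mat Z(static_cast<uword>(npos) * B, K, arma::fill::zeros);
  for (int f = 0; f < fs; ++f) {
    uvec wrows(C);
    for (int c = 0; c < C; ++c) wrows(c) = f + static_cast<uword>(c) * fs;
    Z += gather_offset(Xpad, gidx, f, plane, B) * W.rows(wrows);
  }
  Z.each_row() += bias.t();
  umat mask = Z > 0;
  Z %= arma::conv_to<mat>::from(mask);
  return List::create(_["out"] = Z, _["Xpad"] = Xpad, _["mask"] = mask);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& dOut, const arma::umat& mask,
                  const arma::mat& Xpad, const arma::mat& W,
                  const arma::imat& gidx, const arma::ivec& pad_pos,
                  int plane, int B, bool need_dX) {
  const int npin = pad_pos.n_elem;
  const int C = Xpad.n_cols;
  const int fs = gidx.n_cols;
  const int npos = gidx.n_rows;
  const int K = W.n_cols;
  mat dZ = dOut % arma::conv_to<mat>::from(mask);
  arma::rowvec db = arma::sum(dZ, 0);
  mat dW(static_cast<uword>(fs) * C, K, arma::fill::zeros);
  mat dXpad;
  if (need_dX) dXpad.zeros(static_cast<uword>(plane) * B, C);
  for (int f = 0; f < fs; ++f) {
    uvec wrows(C);
    for (int c = 0; c < C; ++c) wrows(c) = f + static_cast<uword>(c) * fs;
    mat G = gather_offset(Xpad, gidx, f, plane, B);
    dW.rows(wrows) = G.t() * dZ;
    if (need_dX) {
      mat dG = dZ * W.rows(wrows).t();
      for (int c = 0; c < C; ++c) {
        const double* src = dG.colptr(c);
        double* dst = dXpad.colptr(c);
        for (int b = 0; b < B; ++b) {
          const double* srcb = src + static_cast<size_t>(b) * npos;
          double* dstb = dst + static_cast<size_t>(b) * plane;
          for (int q = 0; q < npos; ++q) dstb[gidx(q, f)] += srcb[q];
        }
      }
    }
  }
  List out = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dX) {
    mat dX(static_cast<uword>(npin) * B, C);
    for (int c = 0; c < C; ++c) {
      const double* src = dXpad.colptr(c);
      double* dst = dX.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double* srcb = src + static_cast<size_t>(b) * plane;
        double* dstb = dst + static_cast<size_t>(b) * npin;
        for (int q = 0; q < npin; ++q) dstb[q] = srcb[pad_pos(q)];
      }
    }
    out["dX"] = dX;
  }
  return out;
}

// Max pooling over non-overlapping windows; gidx (npos x fs) holds 0-based
// input-plane indices per (output position, window element).
// [[Rcpp::export]]
List cpp_pool_fwd(const arma::mat& X, const arma::imat& gidx, int npos_in,
                  int B) {
  const int C = X.n_cols;
  const int fs = gidx.n_cols;
  const int npos = gidx.n_rows;
  mat out(static_cast<uword>(npos) * B, C);
  arma::imat amax(static_cast<uword>(npos) * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* srcb = src + static_cast<size_t>(b) * npos_in;
      double* dstb = dst + static_cast<size_t>(b) * npos;
      for (int q = 0; q < npos; ++q) {
        double best = srcb[gidx(q, 0)];
        int barg = 0;
        for (int f = 1; f < fs; ++f) {
          const double v = srcb[gidx(q, f)];
          if (v > best) { best = v; barg = f; }
        }
        dstb[q] = best;
        amax(q + static_cast<uword>(b) * npos, c) = barg;
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat cpp_pool_bwd(const arma::mat& dOut, const arma::imat& amax,
                       const arma::imat& gidx, int npos_in, int B) {
  const int C = dOut.n_cols;
  const int npos = gidx.n_rows;
  mat dX(static_cast<uword>(npos_in) * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = dOut.colptr(c);
    double* dst = dX.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* srcb = src + static_cast<size_t>(b) * npos;
      double* dstb = dst + static_cast<size_t>(b) * npos_in;
      for (int q = 0; q < npos; ++q) {
        dstb[gidx(q, amax(q + static_cast<uword>(b) * npos, c))] += srcb[q];
      }
    }
  }
  return dX;
}
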