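// Low-level image primitives: 2D resampling/warping, 3D connected
// components, boundary extraction and cross-set nearest distances.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sample_bilinear(const arma::mat& img, double si, double sj) {
  const int H = img.n_rows, W = img.n_cols;
  if (si < -0.5 || sj < -0.5 || si > H - 0.5 || sj > W - 0.5) return 0.0;
  int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
  double fi = si - i0, fj = sj - j0;
  int i1 = i0 + 1, j1 = j0 + 1;
  // clamp to valid range; out-of-grid fractions fall back to edge value
  int i0c = std::min(std::max(i0, 0), H - 1), i1c = std::min(std::max(i1, 0), H - 1);
  int j0c = std::min(std::max(j0, 0), W - 1), j1c = std::min(std::max(j1, 0), W - 1);
  double v00 = img(i0c, j0c), v10 = img(i1c, j0c);
  double v01 = img(i0c, j1c), v11 = img(i1c, j1c);
  return (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
         (1 - fi) * fj * v01 + fi * fj * v11;
}

// Resample to (out_h, out_w); pixel centers aligned so that equal sizes give
// the exact identity.
// [[Rcpp::export]]
arma::mat resample_bilinear_cpp(const arma::mat& img, int out_h, int out_w) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(out_h, out_w);
  const double si_scale = (double)H / out_h, sj_scale = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double sj = (j + 0.5) * sj_scale - 0.5;
    for (int i = 0; i < out_h; ++i) {
      double si = (i + 0.5) * si_scale - 0.5;
      out(i, j) = sample_bilinear(img, si, sj);
    }
  }
  return out;
}

// Apply (in forward order) optional flips, rotation about the slice centre,
// then a shift in pixels. Out-of-bounds regions fill with 0. nearest = TRUE
// uses nearest-neighbour sampling (for masks).
// [[Rcpp::export]]
arma::mat warp_slice_cpp(const arma::mat& img, double angle_deg,
                         double shift_i, double shift_j,
                         bool hflip, bool vflip, bool nearest) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W, arma::fill::zeros);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  const double th = -angle_deg * M_PI / 180.0;  // inverse rotation
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double ui = i - shift_i - ci, uj = j - shift_j - cj;
      double si = ct * ui - st * uj + ci;
      double sj = st * ui + ct * uj + cj;
      if (vflip) si = (H - 1) - si;
      if (hflip) sj = (W - 1) - sj;
      if (nearest) {
        int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        if (ii >= 0 && ii < H && jj >= 0 && jj < W) out(i, j) = img(ii, jj);
      } else {
        out(i, j) = sample_bilinear(img, si, sj);
      }
    }
  }
  return out;
}

// 3D connected-component labelling (6- or 26-connectivity), iterative BFS.
// mask: flattened 3D array (column-major), labels returned the same way.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> off_i, off_j, off_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        off_i.push_back(di); off_j.push_back(dj); off_k.push_back(dk);
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
      for (size_t m = 0; m < off_i.size(); ++m) {
        int ii = i + off_i[m], jj = j + off_j[m], kk = k + off_k[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] != 0 && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Boundary voxels: foreground voxels with at least one background 6-neighbour
// (the volume edge counts as background). Returns 1-based (n x 3) indices.
// [[Rcpp::export]]
IntegerMatrix boundary_indices_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> bi, bj, bk;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (mask[p] == 0) continue;
        bool edge = false;
        for (int m = 0; m < 6 && !edge; ++m) {
          int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            edge = true;
          } else {
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] == 0) edge = true;
          }
        }
        if (edge) { bi.push_back(i + 1); bj.push_back(j + 1); bk.push_back(k + 1); }
      }
  IntegerMatrix out(bi.size(), 3);
  for (size_t r = 0; r < bi.size(); ++r) {
    out(r, 0) = bi[r]; out(r, 1) = bj[r]; out(r, 2) = bk[r];
  }
  return out;
}

// For each row of A (points in mm), the Euclidean distance to the nearest
// row of B. Brute force; intended for boundary sets of desk-scale masks.
// [[Rcpp::export]]
NumericVector min_cross_dists_cpp(const arma::mat& A, const arma::mat& B) {
  const arma::uword n = A.n_rows, m = B.n_rows;
  NumericVector out(n);
  for (arma::uword i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (arma::uword j = 0; j < m; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
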