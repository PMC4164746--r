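#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grayscale erosion/dilation by a flat disc structuring element.
// The disc contains offsets (di, dj) with di^2 + dj^2 <= radius^2.
// Pixels outside the image are neutral (ignored), so a flat field stays
// flat up to the border.
//
// Decomposition: the disc is a union of vertical segments, one per column
// offset dj with half-height h(dj). The erosion is then
//   E(i, j) = min_dj V_{h(dj)}(i, j + dj)
// where V_h is the vertical running min with half-window h. All passes scan
// columns, which are contiguous in R's column-major layout.
static NumericMatrix disc_morph(const NumericMatrix& img, double radius,
                                bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const int R = (int)std::floor(radius + 1e-9);
  std::vector<int> halfh(R + 1);
  for (int dj = 0; dj <= R; ++dj) {
    halfh[dj] =
      (int)std::floor(std::sqrt(radius * radius - (double)dj * dj) + 1e-9);
  }
  // distinct half-heights -> index
  std::vector<int> hvals;
  std::vector<int> hidx(R + 1);
  for (int dj = 0; dj <= R; ++dj) {
    int h = halfh[dj], found = -1;
    for (size_t k = 0; k < hvals.size(); ++k)
      if (hvals[k] == h) { found = (int)k; break; }
    if (found < 0) { hvals.push_back(h); found = (int)hvals.size() - 1; }
    hidx[dj] = found;
  }
  // vertical running min/max per distinct half-height
  std::vector<NumericMatrix> V;
  for (size_t k = 0; k < hvals.size(); ++k) {
    int h = hvals[k];
    NumericMatrix M(nr, nc);
    for (int j = 0; j < nc; ++j) {
      const double* col = &img(0, j);
      double* out = &M(0, j);
      for (int i = 0; i < nr; ++i) {
        int i0 = i - h < 0 ? 0 : i - h;
        int i1 = i + h >= nr ? nr - 1 : i + h;
        double v = col[i0];
        if (erode) {
          for (int ii = i0 + 1; ii <= i1; ++ii) if (col[ii] < v) v = col[ii];
        } else {
          for (int ii = i0 + 1; ii <= i1; ++ii) if (col[ii] > v) v = col[ii];
        }
        out[i] = v;
      }
    }
    V.push_back(M);
  }
  // combine across column offsets
  NumericMatrix out(nr, nc);
  double init = erode ? R_PosInf : R_NegInf;
  std::fill(out.begin(), out.end(), init);
  for (int dj = -R; dj <= R; ++dj) {
    const NumericMatrix& M = V[hidx[std::abs(dj)]];
    for (int j = 0; j < nc; ++j) {
      int c = j + dj;
      if (c < 0 || c >= nc) continue;
      const double* src = &M(0, c);
      double* dst = &out(0, j);
      if (erode) {
        for (int i = 0; i < nr; ++i) if (src[i] < dst[i]) dst[i] = src[i];
      } else {
        for (int i = 0; i < nr; ++i) if (src[i] > dst[i]) dst[i] = src[i];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".grey_erode_disc")]]
NumericMatrix grey_erode_disc(NumericMatrix img, double radius) {
  return disc_morph(img, radius, true);
}

// [[Rcpp::export(name = ".grey_dilate_disc")]]
NumericMatrix grey_dilate_disc(NumericMatrix img, double radius) {
  return disc_morph(img, radius, false);
}

// [[Rcpp::export(name = ".grey_tophat_disc")]]
NumericMatrix grey_tophat_disc(NumericMatrix img, double radius) {
  NumericMatrix opened = disc_morph(disc_morph(img, radius, true),
                                    radius, false);
  const int n = img.nrow() * img.ncol();
  NumericMatrix out(img.nrow(), img.ncol());
  for (int k = 0; k < n; ++k) {
    double v = img[k] - opened[k];
    out[k] = v > 0 ? v : 0;
  }
  return out;
}

// Fold background + Gaussian read noise (+ optional Poisson photon noise),
// 12-bit quantisation and clipping into one pass. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".finalize_channel")]]
IntegerMatrix finalize_channel(NumericMatrix signal, double bg_level,
                               double bg_sd, bool photon, int max_dn) {
  const int n = signal.nrow() * signal.ncol();
  IntegerMatrix out(signal.nrow(), signal.ncol());
  RNGScope scope;
  for (int k = 0; k < n; ++k) {
    double v;
    if (photon) {
      v = R::rpois(signal[k] + bg_level);
    } else {
      v = signal[k] + bg_level;
    }
    if (bg_sd > 0) v += R::norm_rand() * bg_sd;
    int q = (int)std::lround(v);
    if (q < 0) q = 0;
    if (q > max_dn) q = max_dn;
    out[k] = q;
  }
  return out;
}

// Rasterise uniform discs onto a zero matrix. Centres and radii are in
// pixel units; a pixel belongs to a disc when its centre lies inside, and
// sub-pixel discs light their anchor pixel so no punctum vanishes.
// Overlapping discs add. Out-of-frame pixels are dropped.
// [[Rcpp::export(name = ".rasterize_discs")]]
NumericMatrix rasterize_discs(NumericVector cx, NumericVector cy,
                              NumericVector r, NumericVector amp,
                              int nr, int nc) {
  NumericMatrix img(nr, nc);
  const int n = cx.size();
  for (int p = 0; p < n; ++p) {
    const double x = cx[p], y = cy[p], rad = r[p], a = amp[p];
    const double r2 = rad * rad;
    int j0 = (int)std::floor(x - rad + 0.5), j1 = (int)std::ceil(x + rad + 0.5);
    int i0 = (int)std::floor(y - rad + 0.5), i1 = (int)std::ceil(y + rad + 0.5);
    bool lit = false;
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j - 0.5) - x;
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i - 0.5) - y;
        if (dx * dx + dy * dy <= r2) {
          if (i >= 1 && i <= nr && j >= 1 && j <= nc) {
            img(i - 1, j - 1) += a;
            lit = true;
          }
        }
      }
    }
    if (!lit) {
      int ai = (int)std::lround(y + 0.5), aj = (int)std::lround(x + 0.5);
      if (ai < 1) ai = 1; if (ai > nr) ai = nr;
      if (aj < 1) aj = 1; if (aj > nc) aj = nc;
      img(ai - 1, aj - 1) += a;
    }
  }
  return img;
}
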