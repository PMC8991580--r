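#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Median filter with edge-replicated borders. Every output value is an
// order statistic of an input window, so the value set is preserved.
// [[Rcpp::export(name = ".cpp_median_filter")]]
NumericMatrix cpp_median_filter(NumericMatrix img, int kernel) {
  const int nr = img.nrow(), nc = img.ncol(), h = kernel / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> win(kernel * kernel);
  const int mid = (kernel * kernel) / 2; // odd count -> true median element
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = 0;
      for (int dc = -h; dc <= h; ++dc) {
        const int cc = clampi(c + dc, 0, nc - 1);
        for (int dr = -h; dr <= h; ++dr)
          win[m++] = img(clampi(r + dr, 0, nr - 1), cc);
      }
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      out(r, c) = win[mid];
    }
  }
  return out;
}

// Bilinear sampling with edge replication; coordinates are 1-based pixel
// centers (r, c) as used throughout the package.
static inline double sample_bilinear(const NumericMatrix &img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  double rr = r - 1.0, cc = c - 1.0; // to 0-based
  if (rr < 0) rr = 0; if (rr > nr - 1) rr = nr - 1;
  if (cc < 0) cc = 0; if (cc > nc - 1) cc = nc - 1;
  const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
  const int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  const double fr = rr - r0, fc = cc - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// [[Rcpp::export(name = ".cpp_sample_bilinear")]]
NumericVector cpp_sample_bilinear(NumericMatrix img, NumericVector r, NumericVector c) {
  const int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_bilinear(img, r[i], c[i]);
  return out;
}

// Outward directional gradient on a radial grid.
// pts: (M*N) x 2 matrix of (row, col), line-major (j fastest);
// units: M x 2 outward unit vectors (row, col). Returns M x N matrix.
// Central differences of the bilinearly sampled image, projected on the ray.
// [[Rcpp::export(name = ".cpp_directional_gradient")]]
NumericMatrix cpp_directional_gradient(NumericMatrix img, NumericMatrix pts,
                                       NumericMatrix units, int n_lines, int n_grad) {
  NumericMatrix g(n_lines, n_grad);
  for (int i = 0; i < n_lines; ++i) {
    const double ur = units(i, 0), uc = units(i, 1);
    for (int j = 0; j < n_grad; ++j) {
      const int idx = i * n_grad + j;
      const double r = pts(idx, 0), c = pts(idx, 1);
      const double dr = 0.5 * (sample_bilinear(img, r + 1, c) - sample_bilinear(img, r - 1, c));
      const double dc = 0.5 * (sample_bilinear(img, r, c + 1) - sample_bilinear(img, r, c - 1));
      g(i, j) = dr * ur + dc * uc;
    }
  }
  return g;
}

// Point-on-segment test with a small absolute tolerance (pixel units).
static inline bool on_segment(double py, double px, double y1, double x1,
                              double y2, double x2, double eps) {
  const double vy = y2 - y1, vx = x2 - x1;
  const double wy = py - y1, wx = px - x1;
  const double len2 = vy * vy + vx * vx;
  if (len2 < eps * eps)
    return std::fabs(wy) <= eps && std::fabs(wx) <= eps;
  double t = (wy * vy + wx * vx) / len2;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dy = wy - t * vy, dx = wx - t * vx;
  return dy * dy + dx * dx <= eps * eps;
}

// Rasterize a closed polygon to a binary mask: pixel-center even-odd rule,
// boundary-inclusive. Vertices are (row, col), 1-based pixel centers.
// [[Rcpp::export(name = ".cpp_polygon_mask")]]
IntegerMatrix cpp_polygon_mask(NumericMatrix verts, int nrow_out, int ncol_out) {
  const int K = verts.nrow();
  IntegerMatrix mask(nrow_out, ncol_out);
  double rmin = R_PosInf, rmax = R_NegInf, cmin = R_PosInf, cmax = R_NegInf;
  for (int k = 0; k < K; ++k) {
    rmin = std::min(rmin, verts(k, 0)); rmax = std::max(rmax, verts(k, 0));
    cmin = std::min(cmin, verts(k, 1)); cmax = std::max(cmax, verts(k, 1));
  }
  const int r0 = clampi((int)std::floor(rmin), 1, nrow_out);
  const int r1 = clampi((int)std::ceil(rmax), 1, nrow_out);
  const int c0 = clampi((int)std::floor(cmin), 1, ncol_out);
  const int c1 = clampi((int)std::ceil(cmax), 1, ncol_out);
  const double eps = 1e-9;
  for (int c = c0; c <= c1; ++c) {
    const double px = (double)c;
    for (int r = r0; r <= r1; ++r) {
      const double py = (double)r;
      bool inside = false, boundary = false;
      for (int k = 0; k < K; ++k) {
        const int k2 = (k + 1) % K;
        const double y1 = verts(k, 0), x1 = verts(k, 1);
        const double y2 = verts(k2, 0), x2 = verts(k2, 1);
        if (on_segment(py, px, y1, x1, y2, x2, eps)) { boundary = true; break; }
        // even-odd crossing along the +col ray
        if ((y1 > py) != (y2 > py)) {
          const double xint = x1 + (py - y1) * (x2 - x1) / (y2 - y1);
          if (px < xint) inside = !inside;
        }
      }
      if (inside || boundary) mask(r - 1, c - 1) = 1;
    }
  }
  return mask;
}
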