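#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher 1D squared distance transform.
// Sites with f == INF carry no parabola; an all-INF row stays INF.
static void edt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (voxel units) from each voxel to the
// nearest zero voxel of `mask`.  Voxels of the zero phase get 0.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *m = LOGICAL(mask);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      edt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = out[base + step * k];
      edt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) out[base + step * k] = d[k];
    }
  return out;
}

// Local thickness by the largest-inscribed-sphere definition.
// At each material voxel c a sphere of radius r(c) = EDT(c) - 0.5 voxels
// (distance to the phase boundary) fits inside the mask; the thickness of
// a voxel is the diameter of the largest such sphere containing it.
// Returns diameters in voxel units; NA outside the mask.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *m = LOGICAL(mask);

  NumericVector d2 = edt_sq_cpp(mask, dims);
  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; ++i)
    r[i] = m[i] ? std::sqrt(d2[i]) - 0.5 : -1.0;

  // prune centers whose sphere lies inside a neighbor's sphere
  std::vector<R_xlen_t> centers;
  centers.reserve(n / 8);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!m[idx]) continue;
        bool redundant = false;
        for (int dk = -1; dk <= 1 && !redundant; ++dk)
          for (int dj = -1; dj <= 1 && !redundant; ++dj)
            for (int di = -1; di <= 1 && !redundant; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                  kk >= nz)
                continue;
              R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (!m[nb]) continue;
              double dist = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[nb] >= r[idx] + dist) redundant = true;
            }
        if (!redundant) centers.push_back(idx);
      }

  // paint largest spheres first
  std::sort(centers.begin(), centers.end(),
            [&r](R_xlen_t a, R_xlen_t b) { return r[a] > r[b]; });

  NumericVector th(n, NA_REAL);
  for (R_xlen_t i = 0; i < n; ++i)
    if (m[i]) th[i] = 0.0;

  for (R_xlen_t ci : centers) {
    const double rc = r[ci];
    const double diam = 2.0 * rc;
    const int i0 = (int)(ci % nx);
    const int j0 = (int)((ci / nx) % ny);
    const int k0 = (int)(ci / ((R_xlen_t)nx * ny));
    const int ri = (int)std::ceil(rc);
    const double r2 = rc * rc;
    for (int dk = -ri; dk <= ri; ++dk) {
      int kk = k0 + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -ri; dj <= ri; ++dj) {
        int jj = j0 + dj;
        if (jj < 0 || jj >= ny) continue;
        double dzy = (double)(dk * dk + dj * dj);
        if (dzy >= r2) continue;
        for (int di = -ri; di <= ri; ++di) {
          int ii = i0 + di;
          if (ii < 0 || ii >= nx) continue;
          if (dzy + di * di < r2) {
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (th[w] < diam) th[w] = diam;
          }
        }
      }
    }
  }
  return th;
}
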