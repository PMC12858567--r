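// Voxel-grid primitives for 3D morphometry: exact squared Euclidean distance
// transform (Felzenszwalb & Huttenlocher lower-envelope algorithm applied
// separably), sphere-fitting local thickness (Hildebrand-Rueegsegger),
// distance-ridge extraction, and 6-connected component labeling.
// Distances are in voxel units; the volume border is treated as open
// (the phase continues past it), so only explicit opposite-phase voxels
// terminate spheres.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e20;

// 1D squared distance transform of sampled function f (length n)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
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
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // 0 where opposite phase, INF where in-phase
  for (R_xlen_t i = 0; i < n; ++i) out[i] = phase[i] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * sz];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * sz] = d[k];
    }
  return out;
}

// Distance ridge: in-phase voxels whose maximal sphere is not contained in
// the maximal sphere of any 26-neighbor (r_nb >= r + |offset| within eps).
// [[Rcpp::export]]
LogicalVector cpp_distance_ridge(NumericVector edt_sq, LogicalVector phase,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector ridge(n);
  const double eps = 1e-9;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (!phase[id]) continue;
        double r = std::sqrt(edt_sq[id]);
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; ++dk)
          for (int dj = -1; dj <= 1 && !dominated; ++dj)
            for (int di = -1; di <= 1 && !dominated; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                continue;
              R_xlen_t nb =
                  (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
              if (!phase[nb]) continue;
              double rn = std::sqrt(edt_sq[nb]);
              double off = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (rn >= r + off - eps) dominated = true;
            }
        ridge[id] = !dominated;
      }
  return ridge;
}

// Sphere-fitting local thickness: th(y) = max over centers x of 2*r(x) such
// that |x - y| <= r(x).  Centers are the ridge voxels (plus a fallback to
// each voxel's own sphere, guaranteeing coverage).  Returns the thickness
// field (voxel units, diameter) over in-phase voxels; 0 elsewhere.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt_sq, LogicalVector phase,
                                  LogicalVector centers, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  struct C { double r2; int i, j, k; };
  std::vector<C> cs;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (centers[id] && phase[id]) cs.push_back({edt_sq[id], i, j, k});
      }
  std::sort(cs.begin(), cs.end(),
            [](const C& a, const C& b) { return a.r2 > b.r2; });
  for (const C& c : cs) {
    double r = std::sqrt(c.r2);
    double dia = 2.0 * r;
    int ir = (int)r;
    for (int dk = -ir; dk <= ir; ++dk) {
      int kk = c.k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        int jj = c.j + dj;
        if (jj < 0 || jj >= ny) continue;
        double rem = c.r2 - dk * dk - dj * dj;
        if (rem < 0) continue;
        int di_max = (int)std::sqrt(rem);
        int ilo = std::max(0, c.i - di_max);
        int ihi = std::min(nx - 1, c.i + di_max);
        R_xlen_t base = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx;
        for (int ii = ilo; ii <= ihi; ++ii) {
          R_xlen_t id = base + ii;
          if (phase[id] && th[id] < dia) th[id] = dia;
        }
      }
    }
  }
  // fallback: every in-phase voxel is at least covered by its own sphere
  for (R_xlen_t id = 0; id < n; ++id)
    if (phase[id]) {
      double dia = 2.0 * std::sqrt(edt_sq[id]);
      if (th[id] < dia) th[id] = dia;
    }
  return th;
}

// 6-connected component labeling (BFS); labels 1..ncomp, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components6(LogicalVector phase, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!phase[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t id = stack.back();
      stack.pop_back();
      int i = id % nx, j = (id / nx) % ny, k = id / ((R_xlen_t)nx * ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (phase[nb] && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}
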