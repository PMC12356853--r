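// Low-level 3D grid kernels: exact Euclidean distance transform and
// connected-component labeling. Grids are column-major (R array layout),
// spacing is per-axis voxel size in mm.
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <queue>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// large finite sentinel for "no feature": keeps the parabola-intersection
// arithmetic free of inf-inf indeterminacy
static const double BIG = 1e15;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s: f is the input cost at positions 0, s, 2s, ...
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double s) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double num = (f[q] + qs * qs);
    double sden;
    while (true) {
      double vs = v[k] * s;
      sden = 2.0 * (qs - vs);
      double sec = (num - (f[v[k]] + vs * vs)) / sden;
      if (sec > z[k]) {
        ++k;
        v[k] = q;
        z[k] = sec;
        z[k + 1] = INF;
        break;
      }
      --k;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest 'feature'
// (non-zero) voxel. Voxels with no feature anywhere give Inf.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector feature, IntegerVector dim,
                    NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // initialize squared distances
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) {
        f[i] = out[base + i];
        if (f[i] < BIG) any = true;
      }
      if (!any) continue;
      dt1d(std::vector<double>(f.begin(), f.begin() + nx), d, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[base + (R_xlen_t)j * nx];
        if (f[j] < BIG) any = true;
      }
      if (!any) continue;
      dt1d(std::vector<double>(f.begin(), f.begin() + ny), d, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  const R_xlen_t pxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[base + k * pxy];
        if (f[k] < BIG) any = true;
      }
      if (!any) continue;
      dt1d(std::vector<double>(f.begin(), f.begin() + nz), d, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + k * pxy] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= BIG / 2) ? INF : std::sqrt(out[i]);
  return out;
}

// Connected components of a 3D foreground mask at 6/18/26 connectivity.
// Labels are assigned in first-touch scan order starting at 1.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbor offsets
  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dx.push_back(a);
        dy.push_back(b);
        dz.push_back(c);
      }
  const int nn = (int)dx.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int m = 0; m < nn; ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
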