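#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas).
// f: input costs, d: output, n: length, v/z: scratch (size n, n+1).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // init: 0 at feature voxels, INF elsewhere
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx, v, z);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, v, z);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + nxy * zz];
      dt1d(f, d, nz, v, z);
      for (int zz = 0; zz < nz; zz++) out[base + nxy * zz] = d[zz];
    }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbourhood offsets
  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; c++)
    for (int b = -1; b <= 1; b++)
      for (int a = -1; a <= 1; a++) {
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int zz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; k++) {
        int xx = x + dx[k], yy = y + dy[k], zc = zz + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zc < 0 || zc >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zc);
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}
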