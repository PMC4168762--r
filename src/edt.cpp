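#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm), run separably along each axis with the axis'
// physical voxel spacing, so anisotropic grids measure true mm distances.

namespace {

// large finite sentinel: avoids INF-INF = NaN inside the envelope update
const double INF = 1e30;

// 1D squared-distance transform of sampled function f at spacing w.
void dt1d(std::vector<double> &f, double w, std::vector<double> &d,
          std::vector<int> &v, std::vector<double> &z) {
  int n = f.size();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double qw = q * w, vw = v[k] * w;
      s = ((f[q] + qw * qw) - (f[v[k]] + vw * vw)) / (2 * qw - 2 * vw);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qw = q * w;
    while (z[k + 1] < qw) ++k;
    double diff = qw - v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
}

} // namespace

// Distance (mm) from each voxel center to the nearest TRUE voxel center.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nvox = (long)nx * ny * nz;
  std::vector<double> g(nvox);
  for (long i = 0; i < nvox; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = (long)nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      f.resize(nx); dt1d(f, spacing[0], d, v, z); f.resize(nmax);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + (long)nx * (j + (long)ny * k)];
      f.resize(ny); dt1d(f, spacing[1], d, v, z); f.resize(nmax);
      for (int j = 0; j < ny; ++j) g[i + (long)nx * (j + (long)ny * k)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[i + (long)nx * (j + (long)ny * k)];
      f.resize(nz); dt1d(f, spacing[2], d, v, z); f.resize(nmax);
      for (int k = 0; k < nz; ++k) g[i + (long)nx * (j + (long)ny * k)] = d[k];
    }

  NumericVector out(nvox);
  for (long i = 0; i < nvox; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
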