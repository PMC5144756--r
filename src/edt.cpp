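#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (lower-envelope-of-parabolas
// algorithm), separable per axis, with anisotropic voxel spacing.
// Cells with no feature carry BIG, large enough to dominate any squared
// physical distance yet safe in double arithmetic.
static const double BIG = 1e18;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, double w) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) --k; else break;
    }
    if (s <= z[k]) { // k == 0: new parabola dominates everywhere
      v[0] = q;
      z[0] = -BIG;
      z[1] = BIG;
      k = 0;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    if (d[q] > BIG) d[q] = BIG;
  }
  f = d;
}

// squared distance (mm^2) from every voxel centre to the nearest voxel
// centre where feature != 0
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq_cpp(NumericVector feature, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = feature[i] != 0 ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), scratch(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  line.resize(nx); scratch.resize(nx);
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      size_t off = (size_t)nx * (y + (size_t)ny * zz);
      for (int x = 0; x < nx; ++x) line[x] = g[off + x];
      dt1d(line, scratch, v, z, spacing[0]);
      for (int x = 0; x < nx; ++x) g[off + x] = line[x];
    }
  line.resize(ny); scratch.resize(ny);
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[x + (size_t)nx * (y + (size_t)ny * zz)];
      dt1d(line, scratch, v, z, spacing[1]);
      for (int y = 0; y < ny; ++y) g[x + (size_t)nx * (y + (size_t)ny * zz)] = line[y];
    }
  line.resize(nz); scratch.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int zz = 0; zz < nz; ++zz) line[zz] = g[x + (size_t)nx * (y + (size_t)ny * zz)];
      dt1d(line, scratch, v, z, spacing[2]);
      for (int zz = 0; zz < nz; ++zz) g[x + (size_t)nx * (y + (size_t)ny * zz)] = line[zz];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}
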