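#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D squared-distance transform, lower-envelope algorithm.
// f: squared distances on entry, d: transformed output.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
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
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `feat`. Voxels with no feature anywhere get Inf.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector feat, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feat[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z (stride nx*ny)
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * sxy];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * sxy] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= DT_INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a 3D logical mask, 6- or 26-connectivity.
// Labels are assigned in first-voxel (column-major) scan order, 1..k.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);

  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a);
        dy.push_back(b);
        dz.push_back(c);
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / sxy);
      int rem = (int)(cur - (R_xlen_t)k * sxy);
      int j = rem / nx;
      int i = rem - j * nx;
      for (size_t m = 0; m < dx.size(); ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)kk * sxy + (R_xlen_t)jj * nx + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static inline double sample_clamped(const NumericVector &src, int nx, int ny,
                                    int nz, int i, int j, int k) {
  i = std::min(std::max(i, 0), nx - 1);
  j = std::min(std::max(j, 0), ny - 1);
  k = std::min(std::max(k, 0), nz - 1);
  return src[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
}

// Resample a 3D grid to new extents; center-aligned coordinate mapping so
// identical extents reproduce the input exactly. nearest=TRUE for label data.
// [[Rcpp::export]]
NumericVector resize3d_cpp(NumericVector src, IntegerVector sdim,
                           IntegerVector ddim, bool nearest = false) {
  int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  int dx = ddim[0], dy = ddim[1], dz = ddim[2];
  NumericVector out((R_xlen_t)dx * dy * dz);
  double rx = (double)sx / dx, ry = (double)sy / dy, rz = (double)sz / dz;
  R_xlen_t idx = 0;
  for (int k = 0; k < dz; ++k) {
    double zc = (k + 0.5) * rz - 0.5;
    for (int j = 0; j < dy; ++j) {
      double yc = (j + 0.5) * ry - 0.5;
      for (int i = 0; i < dx; ++i, ++idx) {
        double xc = (i + 0.5) * rx - 0.5;
        if (nearest) {
          out[idx] = sample_clamped(src, sx, sy, sz, (int)std::floor(xc + 0.5),
                                    (int)std::floor(yc + 0.5),
                                    (int)std::floor(zc + 0.5));
        } else {
          int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc),
              z0 = (int)std::floor(zc);
          double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          double acc = 0.0;
          for (int c = 0; c <= 1; ++c)
            for (int b = 0; b <= 1; ++b)
              for (int a = 0; a <= 1; ++a) {
                double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) *
                           (c ? fz : 1 - fz);
                if (w > 0)
                  acc += w * sample_clamped(src, sx, sy, sz, x0 + a, y0 + b,
                                            z0 + c);
              }
          out[idx] = acc;
        }
      }
    }
  }
  out.attr("dim") = ddim;
  return out;
}

// Separable box mean filter with edge-clamped (shrinking) windows.
// [[Rcpp::export]]
NumericVector boxblur3d_cpp(NumericVector src, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(src.begin(), src.end()), b(n);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> pref(nmax + 1);

  R_xlen_t sxy = (R_xlen_t)nx * ny;
  // helper lambda per axis
  auto pass = [&](int len, R_xlen_t nlines,
                  std::function<R_xlen_t(R_xlen_t, int)> at) {
    for (R_xlen_t l = 0; l < nlines; ++l) {
      pref[0] = 0.0;
      for (int i = 0; i < len; ++i) pref[i + 1] = pref[i] + a[at(l, i)];
      for (int i = 0; i < len; ++i) {
        int lo = std::max(i - radius, 0), hi = std::min(i + radius, len - 1);
        b[at(l, i)] = (pref[hi + 1] - pref[lo]) / (hi - lo + 1);
      }
    }
    std::swap(a, b);
  };

  pass(nx, (R_xlen_t)ny * nz, [&](R_xlen_t l, int i) {
    return l * nx + i;
  });
  pass(ny, (R_xlen_t)nx * nz, [&](R_xlen_t l, int i) {
    R_xlen_t k = l / nx, ii = l % nx;
    return k * sxy + (R_xlen_t)i * nx + ii;
  });
  pass(nz, (R_xlen_t)nx * ny, [&](R_xlen_t l, int i) {
    return (R_xlen_t)i * sxy + l;
  });

  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
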