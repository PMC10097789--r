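#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orthonormal complement of a unit vector w -> (u, v)
static void complement(const double w[3], double u[3], double v[3]) {
  // pick the axis least aligned with w to seed u
  int a = 0;
  if (std::fabs(w[1]) < std::fabs(w[a])) a = 1;
  if (std::fabs(w[2]) < std::fabs(w[a])) a = 2;
  double e[3] = {0.0, 0.0, 0.0};
  e[a] = 1.0;
  double d = e[0]*w[0] + e[1]*w[1] + e[2]*w[2];
  double nu = 0.0;
  for (int i = 0; i < 3; ++i) { u[i] = e[i] - d*w[i]; nu += u[i]*u[i]; }
  nu = std::sqrt(nu);
  for (int i = 0; i < 3; ++i) u[i] /= nu;
  v[0] = w[1]*u[2] - w[2]*u[1];
  v[1] = w[2]*u[0] - w[0]*u[2];
  v[2] = w[0]*u[1] - w[1]*u[0];
}

// Directed line sampling of mean intercept length over an axis-aligned window.
//
// vol: 0/1 values in column-major (R array) order, dims = c(nx, ny, nz).
// lo, hi: 1-based inclusive voxel bounds of the window.
// dirs: n x 3 unit direction matrix.
// line_spacing, step: in voxel units.
// Returns n x 2 matrix: column 1 = total test-line length inside the window
// (voxel units), column 2 = number of bone/marrow transitions.
// [[Rcpp::export]]
NumericMatrix mil_sample_cpp(IntegerVector vol, IntegerVector dims,
                             IntegerVector lo, IntegerVector hi,
                             NumericMatrix dirs, double line_spacing,
                             double step) {
  const int nx = dims[0], ny = dims[1];
  const double lo0[3] = {(double)lo[0] - 1.0, (double)lo[1] - 1.0, (double)lo[2] - 1.0};
  const double hi1[3] = {(double)hi[0], (double)hi[1], (double)hi[2]}; // exclusive
  const double c[3] = {0.5*(lo0[0] + hi1[0]), 0.5*(lo0[1] + hi1[1]), 0.5*(lo0[2] + hi1[2])};
  double hd = 0.0;
  for (int i = 0; i < 3; ++i) {
    double h = 0.5*(hi1[i] - lo0[i]);
    hd += h*h;
  }
  const double R = std::sqrt(hd); // half-diagonal: lines anchored on a disc of this radius
  const int ndir = dirs.nrow();
  NumericMatrix out(ndir, 2);
  const int *pv = INTEGER(vol);

  for (int id = 0; id < ndir; ++id) {
    double w[3] = {dirs(id, 0), dirs(id, 1), dirs(id, 2)};
    double u[3], v[3];
    complement(w, u, v);
    long nin = 0, ncross = 0;
    for (double s = -R; s <= R; s += line_spacing) {
      for (double t = -R; t <= R; t += line_spacing) {
        double o[3];
        for (int i = 0; i < 3; ++i) o[i] = c[i] + s*u[i] + t*v[i];
        int prev = -1;
        for (double q = -R; q <= R; q += step) {
          double p0 = o[0] + q*w[0], p1 = o[1] + q*w[1], p2 = o[2] + q*w[2];
          if (p0 < lo0[0] || p0 >= hi1[0] || p1 < lo0[1] || p1 >= hi1[1] ||
              p2 < lo0[2] || p2 >= hi1[2]) {
            prev = -1;
            continue;
          }
          int i0 = (int)p0, j0 = (int)p1, k0 = (int)p2;
          int val = pv[i0 + nx*(j0 + (long)ny*k0)];
          if (prev >= 0 && val != prev) ++ncross;
          prev = val;
          ++nin;
        }
      }
    }
    out(id, 0) = nin * step;
    out(id, 1) = (double)ncross;
  }
  return out;
}

// In-place style separable Gaussian blur with reflective boundaries.
// x: numeric array values (column-major), dims = c(nx, ny, nz),
// sigma: per-axis standard deviations in voxels (0 disables an axis).
// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector x, IntegerVector dims,
                                  NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cur = clone(x);
  NumericVector tmp(cur.size());
  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, nx, (long)nx*ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0*s);
    std::vector<double> ker(2*rad + 1);
    double sum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      ker[i + rad] = std::exp(-0.5*(double)i*i/(s*s));
      sum += ker[i + rad];
    }
    for (double &kv : ker) kv /= sum;

    const int na = n[ax];
    const long sa = stride[ax];
    const int b = (ax == 0) ? 1 : 0; // remaining two axes
    const int c2 = (ax == 2) ? 1 : 2;
    for (int k = 0; k < n[c2]; ++k) {
      for (int j = 0; j < n[b]; ++j) {
        long base = (long)j*stride[b] + (long)k*stride[c2];
        for (int i = 0; i < na; ++i) {
          double acc = 0.0;
          for (int d = -rad; d <= rad; ++d) {
            int ii = i + d;
            if (ii < 0) ii = -ii - 1;          // reflect
            if (ii >= na) ii = 2*na - ii - 1;
            acc += ker[d + rad]*cur[base + (long)ii*sa];
          }
          tmp[base + (long)i*sa] = acc;
        }
      }
    }
    std::swap(cur, tmp);
  }
  cur.attr("dim") = dims;
  return cur;
}
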