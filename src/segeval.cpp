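#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared Euclidean distance transform by lower envelope of parabolas
// (Felzenszwalb & Huttenlocher). f holds squared distances at samples h apart
// and is overwritten with the transformed values. Columns at +Inf (no seed)
// are skipped so fully empty lines stay at +Inf.
static void dt1d(std::vector<double>& f, int n, double h) {
  if (n == 1) return;
  std::vector<double> d(n, INF), z(n + 1);
  std::vector<int> v(n);
  const double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    while (true) {
      int p = v[k];
      // intersection abscissa in index units
      s = ((f[q] / h2 + (double)q * q) - (f[p] / h2 + (double)p * p)) /
          (2.0 * ((double)q - (double)p));
      if (s <= z[k]) {
        if (--k < 0) break;
      } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) return; // whole line empty
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    int p = v[j];
    double dq = ((double)q - (double)p) * h;
    d[q] = f[p] + dq * dq;
  }
  f.swap(d);
}

//' @name edt_sq_cpp
//' @title Exact squared Euclidean distance transform (internal)
//' @description Squared distance, in mm^2, from every voxel center to the
//'   nearest seed voxel center of a 3D logical array, honoring anisotropic
//'   spacing. Voxels on empty grids are +Inf.
//' @keywords internal
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector ind, NumericVector spacing) {
  IntegerVector dim = ind.attr("dim");
  if (dim.size() != 3) stop("edt_sq_cpp expects a 3D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out(ind.size());
  for (R_xlen_t i = 0; i < ind.size(); ++i)
    out[i] = (ind[i] == TRUE) ? 0.0 : INF;

  std::vector<double> buf;
  // pass along x
  buf.resize(nx);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
      dt1d(buf, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = buf[x];
    }
  }
  // pass along y
  buf.assign(ny, 0.0);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nxy + x;
      for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
      dt1d(buf, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = buf[y];
    }
  }
  // pass along z
  buf.assign(nz, 0.0);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) buf[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(buf, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = buf[z];
    }
  }
  out.attr("dim") = dim;
  return out;
}

//' @name pip_crossings_cpp
//' @title Even-odd polygon crossing counts (internal)
//' @description For each query point, counts ray crossings against the edges
//'   of one closed planar polygon; accumulate over polygons and take parity
//'   for the even-odd rule. The half-open crossing rule ((y1 > py) != (y2 > py),
//'   px strictly left of the intersection) is deterministic for points on
//'   edges or vertices.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector pip_crossings_cpp(NumericVector px, NumericVector py,
                                NumericVector vx, NumericVector vy) {
  const R_xlen_t np = px.size();
  const R_xlen_t nv = vx.size();
  IntegerVector cross(np);
  if (nv < 3) stop("polygon needs at least 3 vertices");
  for (R_xlen_t i = 0; i < np; ++i) {
    const double X = px[i], Y = py[i];
    int c = 0;
    for (R_xlen_t a = 0, b = nv - 1; a < nv; b = a++) {
      const double y1 = vy[a], y2 = vy[b];
      if ((y1 > Y) != (y2 > Y)) {
        const double x1 = vx[a], x2 = vx[b];
        const double xint = x1 + (Y - y1) * (x2 - x1) / (y2 - y1);
        if (X < xint) ++c;
      }
    }
    cross[i] = c;
  }
  return cross;
}
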