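#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays with dim c(nz, ny, nx); linear index iz + nz*(iy + ny*ix).
// All voxel coordinates handed to these kernels are 0-based.

static inline R_xlen_t vidx(int iz, int iy, int ix, int nz, int ny) {
  return (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * ix);
}

static inline double tri_sample(const double* v, int nz, int ny, int nx,
                                double z, double y, double x, double fill) {
  if (!(z >= 0.0 && y >= 0.0 && x >= 0.0 &&
        z <= nz - 1.0 && y <= ny - 1.0 && x <= nx - 1.0))
    return fill;
  int z0 = (int)z, y0 = (int)y, x0 = (int)x;
  if (z0 > nz - 2) z0 = nz - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (x0 > nx - 2) x0 = nx - 2;
  if (z0 < 0) z0 = 0;
  if (y0 < 0) y0 = 0;
  if (x0 < 0) x0 = 0;
  int z1 = (nz > 1) ? z0 + 1 : z0;
  int y1 = (ny > 1) ? y0 + 1 : y0;
  int x1 = (nx > 1) ? x0 + 1 : x0;
  double fz = (nz > 1) ? z - z0 : 0.0;
  double fy = (ny > 1) ? y - y0 : 0.0;
  double fx = (nx > 1) ? x - x0 : 0.0;
  double c000 = v[vidx(z0, y0, x0, nz, ny)], c100 = v[vidx(z1, y0, x0, nz, ny)];
  double c010 = v[vidx(z0, y1, x0, nz, ny)], c110 = v[vidx(z1, y1, x0, nz, ny)];
  double c001 = v[vidx(z0, y0, x1, nz, ny)], c101 = v[vidx(z1, y0, x1, nz, ny)];
  double c011 = v[vidx(z0, y1, x1, nz, ny)], c111 = v[vidx(z1, y1, x1, nz, ny)];
  double c00 = c000 * (1 - fz) + c100 * fz;
  double c10 = c010 * (1 - fz) + c110 * fz;
  double c01 = c001 * (1 - fz) + c101 * fz;
  double c11 = c011 * (1 - fz) + c111 * fz;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

static inline double nn_sample(const double* v, int nz, int ny, int nx,
                               double z, double y, double x, double fill) {
  int iz = (int)std::lround(z), iy = (int)std::lround(y), ix = (int)std::lround(x);
  if (iz < 0 || iy < 0 || ix < 0 || iz >= nz || iy >= ny || ix >= nx) return fill;
  return v[vidx(iz, iy, ix, nz, ny)];
}

// Sample a volume at arbitrary 0-based voxel coordinates.
// pts: N x 3 matrix of (z, y, x); mode 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, int mode, double fill) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = pts(i, 0), y = pts(i, 1), x = pts(i, 2);
    out[i] = (mode == 1) ? nn_sample(v, nz, ny, nx, z, y, x, fill)
                         : tri_sample(v, nz, ny, nx, z, y, x, fill);
  }
  return out;
}

// Mutual information between fixed-image samples fvals and the moving volume
// interpolated at pts (0-based voxel coords in the moving grid). Joint
// histogram with linear (first-order Parzen) weighting on both axes so the
// metric is continuous in the transform parameters. Returns NA when fewer
// than 5% of samples land inside the moving volume (non-overlap diagnostic).
// [[Rcpp::export]]
double cpp_mi_points(NumericVector fvals, NumericVector vol, IntegerVector dim,
                     NumericMatrix pts, int nbins, double fmin, double fmax) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = pts.nrow();
  const double* v = REAL(vol);
  std::vector<double> mv; mv.reserve(n);
  std::vector<double> fv; fv.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = pts(i, 0), y = pts(i, 1), x = pts(i, 2);
    if (z >= 0 && y >= 0 && x >= 0 && z <= nz - 1.0 && y <= ny - 1.0 && x <= nx - 1.0) {
      mv.push_back(tri_sample(v, nz, ny, nx, z, y, x, 0.0));
      fv.push_back(fvals[i]);
    }
  }
  R_xlen_t m = (R_xlen_t)mv.size();
  if (m < 10 || m < (R_xlen_t)(0.05 * n)) return NA_REAL;
  double mmin = mv[0], mmax = mv[0];
  for (R_xlen_t i = 1; i < m; ++i) {
    if (mv[i] < mmin) mmin = mv[i];
    if (mv[i] > mmax) mmax = mv[i];
  }
  if (mmax <= mmin || fmax <= fmin) return 0.0;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  double fscale = (nbins - 1) / (fmax - fmin);
  double mscale = (nbins - 1) / (mmax - mmin);
  for (R_xlen_t i = 0; i < m; ++i) {
    double bf = (fv[i] - fmin) * fscale;
    double bm = (mv[i] - mmin) * mscale;
    if (bf < 0) bf = 0; if (bf > nbins - 1) bf = nbins - 1;
    if (bm < 0) bm = 0; if (bm > nbins - 1) bm = nbins - 1;
    int f0 = (int)bf; if (f0 > nbins - 2) f0 = nbins - 2;
    int m0 = (int)bm; if (m0 > nbins - 2) m0 = nbins - 2;
    double wf = bf - f0, wm = bm - m0;
    joint[(size_t)f0 * nbins + m0]         += (1 - wf) * (1 - wm);
    joint[(size_t)(f0 + 1) * nbins + m0]   += wf * (1 - wm);
    joint[(size_t)f0 * nbins + m0 + 1]     += (1 - wf) * wm;
    joint[(size_t)(f0 + 1) * nbins + m0 + 1] += wf * wm;
  }
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  double tot = (double)m;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double p = joint[(size_t)i * nbins + j] / tot;
      joint[(size_t)i * nbins + j] = p;
      pf[i] += p; pm[j] += p;
    }
  double mi = 0.0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double p = joint[(size_t)i * nbins + j];
      if (p > 1e-12) mi += p * std::log(p / (pf[i] * pm[j]));
    }
  return mi;
}

static void blur_axis(std::vector<double>& a, std::vector<double>& b,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double>& k) {
  int r = (int)(k.size() - 1) / 2;
  int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j = (axis == 0) ? iz + t : (axis == 1) ? iy + t : ix + t;
          // reflect boundary
          if (j < 0) j = -j - 1;
          if (j >= len) j = 2 * len - j - 1;
          if (j < 0) j = 0;
          if (j >= len) j = len - 1;
          int jz = (axis == 0) ? j : iz;
          int jy = (axis == 1) ? j : iy;
          int jx = (axis == 2) ? j : ix;
          acc += k[t + r] * a[vidx(jz, jy, jx, nz, ny)];
        }
        b[vidx(iz, iy, ix, nz, ny)] = acc;
      }
  a.swap(b);
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// Separable Gaussian blur with reflected boundaries; sigma per axis in voxels,
// sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_sep(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
    if (s > 0 && len > 1) blur_axis(a, b, nz, ny, nx, axis, gauss_kernel(s));
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), REAL(out));
  out.attr("dim") = dim;
  return out;
}

// Add isotropic Gaussian blobs: centers N x 3 (z, y, x) 0-based voxel coords,
// per-blob sigma (voxels, isotropic in-plane; divided by zaspect along z) and
// peak amplitude. Returns a modified copy.
// [[Rcpp::export]]
NumericVector cpp_add_blobs(NumericVector vol, IntegerVector dim,
                            NumericMatrix centers, NumericVector sigma,
                            NumericVector amp, double zaspect, double truncate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  double* v = REAL(out);
  for (R_xlen_t b = 0; b < centers.nrow(); ++b) {
    double cz = centers(b, 0), cy = centers(b, 1), cx = centers(b, 2);
    double s = sigma[b], a = amp[b];
    double sz = s / zaspect;
    int rz = std::max(0, (int)std::ceil(truncate * sz));
    int rp = std::max(1, (int)std::ceil(truncate * s));
    int z0 = std::max(0, (int)std::floor(cz) - rz), z1 = std::min(nz - 1, (int)std::ceil(cz) + rz);
    int y0 = std::max(0, (int)std::floor(cy) - rp), y1 = std::min(ny - 1, (int)std::ceil(cy) + rp);
    int x0 = std::max(0, (int)std::floor(cx) - rp), x1 = std::min(nx - 1, (int)std::ceil(cx) + rp);
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy)
        for (int iz = z0; iz <= z1; ++iz) {
          double dz = (iz - cz) / (sz > 0 ? sz : 1.0);
          double dy = (iy - cy) / s, dx = (ix - cx) / s;
          double q = dz * dz * (sz > 0 ? 1.0 : (iz == (int)std::lround(cz) ? 0.0 : 1e9))
                   + dy * dy + dx * dx;
          if (q <= truncate * truncate)
            v[vidx(iz, iy, ix, nz, ny)] += a * std::exp(-0.5 * q);
        }
  }
  out.attr("dim") = dim;
  return out;
}

// 4-connected component labelling of a 2D logical mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(y + ny * x);
      lab(y, x) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int py = p % ny, px = p / ny;
        const int dy[4] = {1, -1, 0, 0}, dx[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int qy = py + dy[d], qx = px + dx[d];
          if (qy < 0 || qx < 0 || qy >= ny || qx >= nx) continue;
          if (mask(qy, qx) && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stack.push_back(qy + ny * qx);
          }
        }
      }
    }
  return lab;
}

static inline void bspline_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Cubic b-spline free-form displacement at arbitrary physical points.
// pts: N x 3 (z,y,x) um; coef: (ncpz*ncpy*ncpx) x 3 control-point
// displacements in um (z fastest). Points outside the control grid support
// are clamped to it.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericMatrix pts, NumericVector origin,
                               NumericVector spacing, IntegerVector ncp,
                               NumericMatrix coef) {
  R_xlen_t n = pts.nrow();
  int nzc = ncp[0], nyc = ncp[1], nxc = ncp[2];
  NumericMatrix out(n, 3);
  double wz[4], wy[4], wx[4];
  for (R_xlen_t i = 0; i < n; ++i) {
    double uz = (pts(i, 0) - origin[0]) / spacing[0];
    double uy = (pts(i, 1) - origin[1]) / spacing[1];
    double ux = (pts(i, 2) - origin[2]) / spacing[2];
    int iz = (int)std::floor(uz), iy = (int)std::floor(uy), ix = (int)std::floor(ux);
    if (iz < 0) iz = 0; if (iz > nzc - 4) iz = nzc - 4;
    if (iy < 0) iy = 0; if (iy > nyc - 4) iy = nyc - 4;
    if (ix < 0) ix = 0; if (ix > nxc - 4) ix = nxc - 4;
    bspline_w(uz - iz, wz); bspline_w(uy - iy, wy); bspline_w(ux - ix, wx);
    double dz = 0, dy = 0, dx = 0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int c = 0; c < 4; ++c) {
          double w = wz[a] * wy[b] * wx[c];
          R_xlen_t k = (R_xlen_t)(iz + a) + (R_xlen_t)nzc * ((iy + b) + (R_xlen_t)nyc * (ix + c));
          dz += w * coef(k, 0); dy += w * coef(k, 1); dx += w * coef(k, 2);
        }
    out(i, 0) = dz; out(i, 1) = dy; out(i, 2) = dx;
  }
  return out;
}
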