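#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column-major linear index for 0-based (i,j,k).
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Trilinear sample at fractional 0-based index (x,y,z); *ok set false when the
// 2x2x2 support leaves the grid.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool *ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *ok = false;
    return 0.0;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1,
      z1 = nz == 1 ? z0 : z0 + 1;
  double c000 = v[lin(x0, y0, z0, nx, ny)], c100 = v[lin(x1, y0, z0, nx, ny)];
  double c010 = v[lin(x0, y1, z0, nx, ny)], c110 = v[lin(x1, y1, z0, nx, ny)];
  double c001 = v[lin(x0, y0, z1, nx, ny)], c101 = v[lin(x1, y0, z1, nx, ny)];
  double c011 = v[lin(x0, y1, z1, nx, ny)], c111 = v[lin(x1, y1, z1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  *ok = true;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nearestnb(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool *ok) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  return v[lin(i, j, k, nx, ny)];
}

// Resample `tgt` onto a grid of dims `odim`; M is the 3x4 affine taking an
// output 0-based index to a fractional 0-based index into tgt.
// [[Rcpp::export]]
List cpp_affine_resample(NumericVector tgt, IntegerVector tdim,
                         IntegerVector odim, NumericMatrix M, int interp) {
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  int onx = odim[0], ony = odim[1], onz = odim[2];
  R_xlen_t n = (R_xlen_t)onx * ony * onz;
  NumericVector out(n);
  LogicalVector valid(n);
  const double *tv = REAL(tgt);
  double a11 = M(0, 0), a12 = M(0, 1), a13 = M(0, 2), b1 = M(0, 3);
  double a21 = M(1, 0), a22 = M(1, 1), a23 = M(1, 2), b2 = M(1, 3);
  double a31 = M(2, 0), a32 = M(2, 1), a33 = M(2, 2), b3 = M(2, 3);
  R_xlen_t p = 0;
  for (int k = 0; k < onz; k++)
    for (int j = 0; j < ony; j++) {
      double xj = a12 * j + a13 * k + b1, yj = a22 * j + a23 * k + b2,
             zj = a32 * j + a33 * k + b3;
      for (int i = 0; i < onx; i++, p++) {
        bool ok;
        double x = a11 * i + xj, y = a21 * i + yj, z = a31 * i + zj;
        double val = interp == 0 ? trilinear(tv, tnx, tny, tnz, x, y, z, &ok)
                                 : nearestnb(tv, tnx, tny, tnz, x, y, z, &ok);
        out[p] = ok ? val : 0.0;
        valid[p] = ok;
      }
    }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Fused resample + sum of squared differences over in-field voxels.
// [[Rcpp::export]]
List cpp_ssd_affine(NumericVector ref, IntegerVector rdim, NumericVector tgt,
                    IntegerVector tdim, NumericMatrix M) {
  int rnx = rdim[0], rny = rdim[1], rnz = rdim[2];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  const double *rv = REAL(ref), *tv = REAL(tgt);
  double a11 = M(0, 0), a12 = M(0, 1), a13 = M(0, 2), b1 = M(0, 3);
  double a21 = M(1, 0), a22 = M(1, 1), a23 = M(1, 2), b2 = M(1, 3);
  double a31 = M(2, 0), a32 = M(2, 1), a33 = M(2, 2), b3 = M(2, 3);
  double ssd = 0.0;
  R_xlen_t nvalid = 0, p = 0;
  for (int k = 0; k < rnz; k++)
    for (int j = 0; j < rny; j++) {
      double xj = a12 * j + a13 * k + b1, yj = a22 * j + a23 * k + b2,
             zj = a32 * j + a33 * k + b3;
      for (int i = 0; i < rnx; i++, p++) {
        bool ok;
        double g = trilinear(tv, tnx, tny, tnz, a11 * i + xj, a21 * i + yj,
                             a31 * i + zj, &ok);
        if (ok) {
          double d = rv[p] - g;
          ssd += d * d;
          nvalid++;
        }
      }
    }
  return List::create(_["ssd"] = ssd, _["n"] = (double)nvalid);
}

// Direct (triple-loop) linear convolution of x with an odd-sided kernel,
// zero padding, output cropped to the size of x. Independent oracle for the
// FFT path and brute-force dose reference.
// [[Rcpp::export]]
NumericVector cpp_conv3_direct(NumericVector x, IntegerVector xdim,
                               NumericVector kern, IntegerVector kdim) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *xv = REAL(x), *kv = REAL(kern);
  double *ov = REAL(out);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double s = xv[lin(i, j, k, nx, ny)];
        if (s == 0.0) continue;
        for (int w = 0; w < kz; w++) {
          int zz = k + w - cz;
          if (zz < 0 || zz >= nz) continue;
          for (int v = 0; v < ky; v++) {
            int yy = j + v - cy;
            if (yy < 0 || yy >= ny) continue;
            for (int u = 0; u < kx; u++) {
              int xx = i + u - cx;
              if (xx < 0 || xx >= nx) continue;
              ov[lin(xx, yy, zz, nx, ny)] += s * kv[lin(u, v, w, kx, ky)];
            }
          }
        }
      }
  return out;
}

// Fused resample + SSD over a fixed subset of reference voxels (0-based
// linear indices). Using a support mask fixed in the reference frame keeps
// the cost continuous when the transform crosses grid-aligned positions
// (the full-grid valid set changes discontinuously there).
// [[Rcpp::export]]
List cpp_ssd_affine_mask(NumericVector ref, IntegerVector rdim,
                         NumericVector tgt, IntegerVector tdim,
                         NumericMatrix M, IntegerVector idx) {
  int rnx = rdim[0], rny = rdim[1];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  const double *rv = REAL(ref), *tv = REAL(tgt);
  double a11 = M(0, 0), a12 = M(0, 1), a13 = M(0, 2), b1 = M(0, 3);
  double a21 = M(1, 0), a22 = M(1, 1), a23 = M(1, 2), b2 = M(1, 3);
  double a31 = M(2, 0), a32 = M(2, 1), a33 = M(2, 2), b3 = M(2, 3);
  double ssd = 0.0;
  R_xlen_t nvalid = 0;
  for (R_xlen_t q = 0; q < idx.size(); q++) {
    R_xlen_t p = idx[q];
    int i = (int)(p % rnx), j = (int)((p / rnx) % rny),
        k = (int)(p / ((R_xlen_t)rnx * rny));
    bool ok;
    double g = trilinear(tv, tnx, tny, tnz,
                         a11 * i + a12 * j + a13 * k + b1,
                         a21 * i + a22 * j + a23 * k + b2,
                         a31 * i + a32 * j + a33 * k + b3, &ok);
    if (ok) {
      double d = rv[p] - g;
      ssd += d * d;
      nvalid++;
    }
  }
  return List::create(_["ssd"] = ssd, _["n"] = (double)nvalid);
}

// 26-connectivity labelling of a boolean mask (iterative BFS).
// Labels are 1..ncomp in discovery (lowest-linear-index) order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t q = queue.back();
      queue.pop_back();
      int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t q2 = lin(ii, jj, kk, nx, ny);
            if (mask[q2] && lab[q2] == 0) {
              lab[q2] = next;
              queue.push_back(q2);
            }
          }
    }
  }
  return lab;
}
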