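#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear / nearest-neighbour resampling of a 3D volume through a 4x4
// homogeneous matrix acting on physical (mm) coordinates. The matrix maps
// reference-space points into moving space (pull-back convention): each
// output voxel takes the moving image's value at M * x_ref.
// [[Rcpp::export]]
NumericVector cpp_resample(const NumericVector& mov, const IntegerVector& mdim,
                           const NumericVector& msp, const NumericVector& morg,
                           const IntegerVector& rdim, const NumericVector& rsp,
                           const NumericVector& rorg, const NumericVector& M,
                           int interp, double fill) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const int rx = rdim[0], ry = rdim[1], rz = rdim[2];
  NumericVector out((R_xlen_t)rx * ry * rz);
  // M is 4x4 column-major; only the top three rows matter
  const double m00 = M[0], m10 = M[1], m20 = M[2];
  const double m01 = M[4], m11 = M[5], m21 = M[6];
  const double m02 = M[8], m12 = M[9], m22 = M[10];
  const double m03 = M[12], m13 = M[13], m23 = M[14];
  const double isx = 1.0 / msp[0], isy = 1.0 / msp[1], isz = 1.0 / msp[2];
  R_xlen_t o = 0;
  for (int k = 0; k < rz; ++k) {
    const double zp0 = rorg[2] + k * rsp[2];
    for (int j = 0; j < ry; ++j) {
      const double yp = rorg[1] + j * rsp[1];
      const double cx = m01 * yp + m02 * zp0 + m03;
      const double cy = m11 * yp + m12 * zp0 + m13;
      const double cz = m21 * yp + m22 * zp0 + m23;
      for (int i = 0; i < rx; ++i, ++o) {
        const double xp = rorg[0] + i * rsp[0];
        const double u = (m00 * xp + cx - morg[0]) * isx;
        const double v = (m10 * xp + cy - morg[1]) * isy;
        const double w = (m20 * xp + cz - morg[2]) * isz;
        if (interp == 0) {  // nearest
          const int iu = (int)std::lround(u), iv = (int)std::lround(v),
                    iw = (int)std::lround(w);
          if (iu < 0 || iu >= nx || iv < 0 || iv >= ny || iw < 0 || iw >= nz) {
            out[o] = fill;
          } else {
            out[o] = mov[(R_xlen_t)iu + (R_xlen_t)nx * (iv + (R_xlen_t)ny * iw)];
          }
        } else {  // trilinear
          if (u < 0 || u > nx - 1 || v < 0 || v > ny - 1 || w < 0 || w > nz - 1) {
            out[o] = fill;
            continue;
          }
          int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
          if (i0 == nx - 1) i0--;
          if (j0 == ny - 1) j0--;
          if (k0 == nz - 1) k0--;
          if (nx == 1) i0 = 0;
          if (ny == 1) j0 = 0;
          if (nz == 1) k0 = 0;
          const double fu = u - i0, fv = v - j0, fw = w - k0;
          const int i1 = (nx == 1) ? i0 : i0 + 1;
          const int j1 = (ny == 1) ? j0 : j0 + 1;
          const int k1 = (nz == 1) ? k0 : k0 + 1;
          const R_xlen_t sxy = (R_xlen_t)nx * ny;
          const double c000 = mov[i0 + (R_xlen_t)nx * j0 + sxy * k0];
          const double c100 = mov[i1 + (R_xlen_t)nx * j0 + sxy * k0];
          const double c010 = mov[i0 + (R_xlen_t)nx * j1 + sxy * k0];
          const double c110 = mov[i1 + (R_xlen_t)nx * j1 + sxy * k0];
          const double c001 = mov[i0 + (R_xlen_t)nx * j0 + sxy * k1];
          const double c101 = mov[i1 + (R_xlen_t)nx * j0 + sxy * k1];
          const double c011 = mov[i0 + (R_xlen_t)nx * j1 + sxy * k1];
          const double c111 = mov[i1 + (R_xlen_t)nx * j1 + sxy * k1];
          const double c00 = c000 * (1 - fu) + c100 * fu;
          const double c10 = c010 * (1 - fu) + c110 * fu;
          const double c01 = c001 * (1 - fu) + c101 * fu;
          const double c11 = c011 * (1 - fu) + c111 * fu;
          const double c0 = c00 * (1 - fv) + c10 * fv;
          const double c1 = c01 * (1 - fv) + c11 * fv;
          out[o] = c0 * (1 - fw) + c1 * fw;
        }
      }
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v;
    s += v;
  }
  for (auto& v : k) v /= s;
}

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing with reflective boundaries; sigma per axis
// in voxel units (sigma <= 0 skips that axis).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(const NumericVector& vol, const IntegerVector& dim,
                               const NumericVector& sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, sxy = (R_xlen_t)nx * ny;
  NumericVector a = clone(vol);
  std::vector<double> ker, tmp;
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    gauss_kernel(sigma[ax], ker);
    const int r = ((int)ker.size() - 1) / 2;
    NumericVector b(n);
    const int len = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t idx = i + (R_xlen_t)nx * j + sxy * k;
          double acc = 0.0;
          for (int d = -r; d <= r; ++d) {
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = reflect(i + d, len);
            else if (ax == 1) jj = reflect(j + d, len);
            else kk = reflect(k + d, len);
            acc += ker[d + r] * a[ii + (R_xlen_t)nx * jj + sxy * kk];
          }
          b[idx] = acc;
        }
    a = b;
  }
  return a;
}

// Connected-component labelling of a binary volume, 26- or 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const IntegerVector& mask, const IntegerVector& dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, sxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int k = (int)(c / sxy), j = (int)((c % sxy) / nx), i = (int)(c % nx);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1)
              continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const R_xlen_t q = ii + (R_xlen_t)nx * jj + sxy * kk;
            if (mask[q] != 0 && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Morphological dilation by an explicit offset set (voxel offsets, n x 3).
// Out-of-bounds neighbours are treated as background.
// [[Rcpp::export]]
IntegerVector cpp_dilate(const IntegerVector& mask, const IntegerVector& dim,
                         const IntegerMatrix& offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  IntegerVector out((R_xlen_t)nx * ny * nz, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * j + sxy * k;
        int hit = 0;
        for (int m = 0; m < offsets.nrow() && !hit; ++m) {
          const int ii = i + offsets(m, 0), jj = j + offsets(m, 1),
                    kk = k + offsets(m, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          if (mask[ii + (R_xlen_t)nx * jj + sxy * kk] != 0) hit = 1;
        }
        out[idx] = hit;
      }
  return out;
}

// Fill internal cavities: background voxels not 6-connected to the volume
// boundary become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(const IntegerVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, sxy = (R_xlen_t)nx * ny;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1)
          continue;
        const R_xlen_t idx = i + (R_xlen_t)nx * j + sxy * k;
        if (mask[idx] == 0 && !outside[idx]) {
          outside[idx] = 1;
          stack.push_back(idx);
        }
      }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    const R_xlen_t c = stack.back();
    stack.pop_back();
    const int k = (int)(c / sxy), j = (int)((c % sxy) / nx), i = (int)(c % nx);
    for (int m = 0; m < 6; ++m) {
      const int ii = i + d6[m][0], jj = j + d6[m][1], kk = k + d6[m][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      const R_xlen_t q = ii + (R_xlen_t)nx * jj + sxy * kk;
      if (mask[q] == 0 && !outside[q]) {
        outside[q] = 1;
        stack.push_back(q);
      }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (mask[s] != 0 || !outside[s]) ? 1 : 0;
  return out;
}
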