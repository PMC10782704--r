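#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3-D array at continuous 0-based voxel index (x,y,z).
// Outside the grid support the sample is invalid (inside = false).
static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, bool &inside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) fx = 0;
  if (ny == 1) fy = 0;
  if (nz == 1) fz = 0;
  int x1 = (nx == 1) ? x0 : x0 + 1;
  int y1 = (ny == 1) ? y0 : y0 + 1;
  int z1 = (nz == 1) ? z0 : z0 + 1;
#define IDX(i, j, k) ((i) + (size_t)nx * ((j) + (size_t)ny * (k)))
  double c000 = v[IDX(x0, y0, z0)], c100 = v[IDX(x1, y0, z0)];
  double c010 = v[IDX(x0, y1, z0)], c110 = v[IDX(x1, y1, z0)];
  double c001 = v[IDX(x0, y0, z1)], c101 = v[IDX(x1, y0, z1)];
  double c011 = v[IDX(x0, y1, z1)], c111 = v[IDX(x1, y1, z1)];
#undef IDX
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nn_sample(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool &inside) {
  // half-voxel tolerance so boundary voxel centers stay valid
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz ||
      x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
    inside = false;
    return 0.0;
  }
  inside = true;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

// Resample src onto a target grid. `affine` is a 3x4 matrix mapping target
// physical coordinates to source physical coordinates (identity for plain
// grid resampling; the inverse rigid transform when applying a transform).
// [[Rcpp::export]]
List cpp_resample(NumericVector src, IntegerVector sdim, NumericVector sspc,
                  NumericVector sorg, IntegerVector tdim, NumericVector tspc,
                  NumericVector torg, NumericMatrix affine, bool nearest,
                  double fill) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  NumericVector out((size_t)tnx * tny * tnz);
  const double *sv = REAL(src);
  double a[3][4];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) a[r][c] = affine(r, c);
  size_t n_out = 0, idx = 0;
  for (int k = 0; k < tnz; k++) {
    double pz = torg[2] + k * tspc[2];
    for (int j = 0; j < tny; j++) {
      double py = torg[1] + j * tspc[1];
      for (int i = 0; i < tnx; i++, idx++) {
        double px = torg[0] + i * tspc[0];
        double qx = a[0][0] * px + a[0][1] * py + a[0][2] * pz + a[0][3];
        double qy = a[1][0] * px + a[1][1] * py + a[1][2] * pz + a[1][3];
        double qz = a[2][0] * px + a[2][1] * py + a[2][2] * pz + a[2][3];
        double x = (qx - sorg[0]) / sspc[0];
        double y = (qy - sorg[1]) / sspc[1];
        double z = (qz - sorg[2]) / sspc[2];
        bool inside;
        double val = nearest ? nn_sample(sv, snx, sny, snz, x, y, z, inside)
                             : tri_sample(sv, snx, sny, snz, x, y, z, inside);
        if (!inside) {
          out[idx] = fill;
          n_out++;
        } else {
          out[idx] = val;
        }
      }
    }
  }
  return List::create(_["values"] = out, _["n_outside"] = (double)n_out);
}

// Separable Gaussian smoothing; sigma in voxel units per axis, truncated at
// 3 sigma, kernel renormalised at the edges.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector src, IntegerVector dim,
                          NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> buf1(REAL(src), REAL(src) + n), buf2(n);
  int nd[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int axis = 0; axis < 3; axis++) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int t = -r; t <= r; t++) kern[t + r] = std::exp(-0.5 * t * t / (s * s));
    int na = nd[axis];
    size_t st = stride[axis];
    // iterate over all lines along `axis`
    int d1 = (axis == 0) ? 1 : 0;
    int d2 = (axis == 2) ? 1 : 2;
    for (int c2 = 0; c2 < nd[d2]; c2++) {
      for (int c1 = 0; c1 < nd[d1]; c1++) {
        size_t base = (size_t)c1 * stride[d1] + (size_t)c2 * stride[d2];
        for (int p = 0; p < na; p++) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, p - r), hi = std::min(na - 1, p + r);
          for (int q = lo; q <= hi; q++) {
            double w = kern[q - p + r];
            acc += w * buf1[base + (size_t)q * st];
            wsum += w;
          }
          buf2[base + (size_t)p * st] = acc / wsum;
        }
      }
    }
    std::swap(buf1, buf2);
  }
  NumericVector out(n);
  std::copy(buf1.begin(), buf1.end(), REAL(out));
  return out;
}
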