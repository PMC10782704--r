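#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Distance (mm) from each query-grid voxel centre to the nearest surface
// voxel centre of a binary mask (0 inside the mask). Brute force over the
// mask's surface voxels; intended for the analytic dose fallback when a PTV
// is not a generated sphere.
// [[Rcpp::export]]
NumericVector cpp_dist_outside(IntegerVector mask, IntegerVector mdim,
                               NumericVector mspc, NumericVector morg,
                               IntegerVector qdim, NumericVector qspc,
                               NumericVector qorg) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const int *mv = INTEGER(mask);
  std::vector<double> sx, sy, sz;
  auto at = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return mv[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
  };
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!at(i, j, k)) continue;
        if (!at(i - 1, j, k) || !at(i + 1, j, k) || !at(i, j - 1, k) ||
            !at(i, j + 1, k) || !at(i, j, k - 1) || !at(i, j, k + 1)) {
          sx.push_back(morg[0] + i * mspc[0]);
          sy.push_back(morg[1] + j * mspc[1]);
          sz.push_back(morg[2] + k * mspc[2]);
        }
      }
  size_t ns = sx.size();
  int qnx = qdim[0], qny = qdim[1], qnz = qdim[2];
  NumericVector out((size_t)qnx * qny * qnz);
  size_t idx = 0;
  for (int k = 0; k < qnz; k++) {
    double pz = qorg[2] + k * qspc[2];
    for (int j = 0; j < qny; j++) {
      double py = qorg[1] + j * qspc[1];
      for (int i = 0; i < qnx; i++, idx++) {
        double px = qorg[0] + i * qspc[0];
        double best = R_PosInf;
        for (size_t s = 0; s < ns; s++) {
          double dx = px - sx[s], dy = py - sy[s], dz = pz - sz[s];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}
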