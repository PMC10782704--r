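#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared trilinear sampler (physical-space search uses continuous indices).
static inline double tri3(const double *v, int nx, int ny, int nz, double x,
                          double y, double z, bool &inside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = std::min((int)std::floor(x), nx - 2);
  int y0 = std::min((int)std::floor(y), ny - 2);
  int z0 = std::min((int)std::floor(z), nz - 2);
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = (nx == 1) ? 0 : x - x0;
  double fy = (ny == 1) ? 0 : y - y0;
  double fz = (nz == 1) ? 0 : z - z0;
  int x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1,
      z1 = (nz == 1) ? z0 : z0 + 1;
#define IDX(i, j, k) ((i) + (size_t)nx * ((j) + (size_t)ny * (k)))
  double c00 = v[IDX(x0, y0, z0)] * (1 - fx) + v[IDX(x1, y0, z0)] * fx;
  double c10 = v[IDX(x0, y1, z0)] * (1 - fx) + v[IDX(x1, y1, z0)] * fx;
  double c01 = v[IDX(x0, y0, z1)] * (1 - fx) + v[IDX(x1, y0, z1)] * fx;
  double c11 = v[IDX(x0, y1, z1)] * (1 - fx) + v[IDX(x1, y1, z1)] * fx;
#undef IDX
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

struct Offset {
  double dx, dy, dz, r2;
};

static std::vector<Offset> lattice_offsets(double step, double radius) {
  std::vector<Offset> offs;
  int m = (int)std::floor(radius / step + 1e-9);
  double r2max = radius * radius + 1e-12;
  for (int k = -m; k <= m; k++)
    for (int j = -m; j <= m; j++)
      for (int i = -m; i <= m; i++) {
        double dx = i * step, dy = j * step, dz = k * step;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= r2max) offs.push_back({dx, dy, dz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.r2 < b.r2; });
  return offs;
}

// Branch-and-bound gamma search context for one reference voxel.
// Boxes live in eval-grid continuous index coordinates. The evaluated dose
// is trilinear within each grid cell, so its min/max over any box contained
// in one cell are attained at the box corners -- corner bounds are exact
// and the search is certified to the stop tolerance.
struct GammaCtx {
  const double *ev;
  int enx, eny, enz;
  double eorg[3], espc[3];
  double px, py, pz; // reference position (mm)
  double dref, dta2, dd2;
  double r2max;      // search radius^2 (mm^2)
  double best;       // current best gamma^2
  double early_g2;   // bound above which gamma^2 need not be exact
  double tol_gamma;  // certification tolerance in gamma units
  double ax, ay, az; // physical offset of the best candidate (argmin)
};

static inline double box_dist2(const GammaCtx &c, const double lo[3],
                               const double hi[3]) {
  double d2 = 0;
  double p[3] = {c.px, c.py, c.pz};
  for (int a = 0; a < 3; a++) {
    double plo = c.eorg[a] + lo[a] * c.espc[a];
    double phi = c.eorg[a] + hi[a] * c.espc[a];
    double d = 0;
    if (p[a] < plo) d = plo - p[a];
    else if (p[a] > phi) d = p[a] - phi;
    d2 += d * d;
  }
  return d2;
}

static void bnb_box(GammaCtx &c, const double lo[3], const double hi[3]) {
  double d2 = box_dist2(c, lo, hi);
  if (d2 > c.r2max) return;
  double dist_term = d2 / c.dta2;
  if (dist_term >= c.best) return;
  // corner dose bounds (exact: trilinear within a single cell)
  double cmin = R_PosInf, cmax = R_NegInf;
  for (int q = 0; q < 8; q++) {
    double x = (q & 1) ? hi[0] : lo[0];
    double y = (q & 2) ? hi[1] : lo[1];
    double z = (q & 4) ? hi[2] : lo[2];
    bool inside;
    double d = tri3(c.ev, c.enx, c.eny, c.enz, x, y, z, inside);
    if (!inside) continue; // clipped boxes are always inside; safety only
    cmin = std::min(cmin, d);
    cmax = std::max(cmax, d);
    // corner is also a candidate point
    double ppx = c.eorg[0] + x * c.espc[0] - c.px;
    double ppy = c.eorg[1] + y * c.espc[1] - c.py;
    double ppz = c.eorg[2] + z * c.espc[2] - c.pz;
    double r2 = ppx * ppx + ppy * ppy + ppz * ppz;
    if (r2 <= c.r2max) {
      double dd = d - c.dref;
      double g2 = r2 / c.dta2 + dd * dd / c.dd2;
      if (g2 < c.best) {
        c.best = g2;
        c.ax = ppx;
        c.ay = ppy;
        c.az = ppz;
      }
    }
  }
  if (!R_FINITE(cmin)) return;
  double gap = 0;
  if (c.dref < cmin) gap = cmin - c.dref;
  else if (c.dref > cmax) gap = c.dref - cmax;
  double lower = dist_term + gap * gap / c.dd2;
  // stop when the box cannot change the pass decision (early_g2) or cannot
  // improve gamma by more than tol_gamma (the gamma^2 gap 2*tol*sqrt(best)
  // corresponds to a gamma gap of tol near the current best), or is
  // vanishingly small
  if (lower >= c.early_g2) return;
  double tol_g2 = 2 * c.tol_gamma * std::sqrt(std::max(c.best, 1e-12)) +
                  c.tol_gamma * c.tol_gamma;
  // a box is ambiguous while it could still flip the pass decision at
  // gamma = 1; keep refining those so pass/fail is exact at any tolerance
  bool ambiguous = (lower < 1.0 && c.best >= 1.0);
  if (!ambiguous && lower >= c.best - tol_g2) return;
  double sz = 0;
  for (int a = 0; a < 3; a++)
    sz = std::max(sz, (hi[a] - lo[a]) * c.espc[a]);
  if (sz < 0.005) return;
  double mid[3] = {(lo[0] + hi[0]) / 2, (lo[1] + hi[1]) / 2,
                   (lo[2] + hi[2]) / 2};
  // recurse nearest children first so the running best converges before
  // distant siblings are examined (they then prune immediately)
  double slo[8][3], shi[8][3], pr[8];
  int ord[8];
  for (int q = 0; q < 8; q++) {
    slo[q][0] = (q & 1) ? mid[0] : lo[0];
    shi[q][0] = (q & 1) ? hi[0] : mid[0];
    slo[q][1] = (q & 2) ? mid[1] : lo[1];
    shi[q][1] = (q & 2) ? hi[1] : mid[1];
    slo[q][2] = (q & 4) ? mid[2] : lo[2];
    shi[q][2] = (q & 4) ? hi[2] : mid[2];
    pr[q] = box_dist2(c, slo[q], shi[q]);
    ord[q] = q;
  }
  std::sort(ord, ord + 8, [&](int a, int b) { return pr[a] < pr[b]; });
  for (int t = 0; t < 8; t++) bnb_box(c, slo[ord[t]], shi[ord[t]]);
}

// 3-D gamma index. dd_frac: dose criterion as a fraction (0.01 = 1%);
// dta_mm: distance-to-agreement; local: local vs global normalisation;
// threshold_frac: reference voxels below threshold_frac * max(ref) are
// excluded (returned as NA). The evaluated dose is searched within
// search_factor * dta of each reference voxel by branch-and-bound over the
// trilinear interpolation cells; subdivision stops when a box cannot
// improve the running best by more than a ~1e-3 relative gap in gamma^2,
// so the returned minimum is certified to that tolerance. Values whose
// gamma^2 lower bound exceeds early_g2 may be reported as upper bounds
// (set early_g2 = Inf for a fully certified map).
// [[Rcpp::export]]
List cpp_gamma(NumericVector ref, IntegerVector rdim,
                        NumericVector rspc, NumericVector rorg,
                        NumericVector ev, IntegerVector edim,
                        NumericVector espc, NumericVector eorg, double dd_frac,
                        double dta_mm, bool local, double threshold_frac,
                        double search_factor, double early_g2,
                        double tol_gamma) {
  int rnx = rdim[0], rny = rdim[1], rnz = rdim[2];
  const double *rv = REAL(ref);
  size_t nref = (size_t)rnx * rny * rnz;
  double refmax = 0;
  for (size_t i = 0; i < nref; i++) refmax = std::max(refmax, rv[i]);
  double thresh = threshold_frac * refmax;
  double radius = search_factor * dta_mm;

  GammaCtx c;
  c.ev = REAL(ev);
  c.enx = edim[0]; c.eny = edim[1]; c.enz = edim[2];
  for (int a = 0; a < 3; a++) {
    c.eorg[a] = eorg[a];
    c.espc[a] = espc[a];
  }
  c.dta2 = dta_mm * dta_mm;
  c.r2max = radius * radius;
  c.early_g2 = early_g2;
  c.tol_gamma = tol_gamma;

  NumericVector out(nref);
  NumericMatrix arg(3, nref);
  std::fill(arg.begin(), arg.end(), NA_REAL);
  size_t idx = 0;
  for (int k = 0; k < rnz; k++) {
    double pz = rorg[2] + k * rspc[2];
    for (int j = 0; j < rny; j++) {
      double py = rorg[1] + j * rspc[1];
      for (int i = 0; i < rnx; i++, idx++) {
        double dref = rv[idx];
        if (dref < thresh || (local && dref <= 0)) {
          out[idx] = NA_REAL;
          continue;
        }
        double delta = dd_frac * (local ? dref : refmax);
        c.dd2 = delta * delta;
        c.dref = dref;
        c.px = rorg[0] + i * rspc[0];
        c.py = py;
        c.pz = pz;
        c.best = R_PosInf;
        c.ax = c.ay = c.az = NA_REAL;
        // cell range intersecting the search ball
        int lo_i[3], hi_i[3];
        double p[3] = {c.px, c.py, c.pz};
        int en[3] = {c.enx, c.eny, c.enz};
        bool any = true;
        for (int a = 0; a < 3; a++) {
          lo_i[a] = (int)std::floor((p[a] - radius - c.eorg[a]) / c.espc[a]);
          hi_i[a] = (int)std::ceil((p[a] + radius - c.eorg[a]) / c.espc[a]);
          lo_i[a] = std::max(lo_i[a], 0);
          hi_i[a] = std::min(hi_i[a], en[a] - 1);
          if (lo_i[a] >= hi_i[a]) {
            // degenerate axis (single plane): keep a zero-width box
            if (lo_i[a] > hi_i[a]) any = false;
          }
        }
        if (!any) {
          out[idx] = R_PosInf;
          continue;
        }
        // seed with the zero-offset candidate so pruning bites immediately
        {
          bool inside;
          double x = (c.px - c.eorg[0]) / c.espc[0];
          double y = (c.py - c.eorg[1]) / c.espc[1];
          double z = (c.pz - c.eorg[2]) / c.espc[2];
          double de = tri3(c.ev, c.enx, c.eny, c.enz, x, y, z, inside);
          if (inside) {
            double dd = de - dref;
            c.best = dd * dd / c.dd2;
            c.ax = c.ay = c.az = 0;
          }
        }
        // cells sorted by distance so the best drops before far cells
        struct CellRef { double d2; int ci, cj, ck; };
        std::vector<CellRef> cells;
        for (int ck = lo_i[2]; ck <= std::max(hi_i[2] - 1, lo_i[2]); ck++)
          for (int cj = lo_i[1]; cj <= std::max(hi_i[1] - 1, lo_i[1]); cj++)
            for (int ci = lo_i[0]; ci <= std::max(hi_i[0] - 1, lo_i[0]); ci++) {
              double blo[3] = {(double)ci, (double)cj, (double)ck};
              double bhi[3] = {std::min((double)ci + 1, (double)(en[0] - 1)),
                               std::min((double)cj + 1, (double)(en[1] - 1)),
                               std::min((double)ck + 1, (double)(en[2] - 1))};
              double d2 = box_dist2(c, blo, bhi);
              if (d2 <= c.r2max) cells.push_back({d2, ci, cj, ck});
            }
        std::sort(cells.begin(), cells.end(),
                  [](const CellRef &a, const CellRef &b) { return a.d2 < b.d2; });
        for (const CellRef &cr : cells) {
          if (cr.d2 / c.dta2 >= std::min(c.best, c.early_g2)) break;
          double blo[3] = {(double)cr.ci, (double)cr.cj, (double)cr.ck};
          double bhi[3] = {std::min((double)cr.ci + 1, (double)(en[0] - 1)),
                           std::min((double)cr.cj + 1, (double)(en[1] - 1)),
                           std::min((double)cr.ck + 1, (double)(en[2] - 1))};
          bnb_box(c, blo, bhi);
        }
        out[idx] = R_FINITE(c.best) ? std::sqrt(c.best) : R_PosInf;
        arg(0, idx) = c.ax;
        arg(1, idx) = c.ay;
        arg(2, idx) = c.az;
      }
    }
  }
  return List::create(_["gamma"] = out, _["argmin"] = arg);
}

// Independent oracle: exhaustive search over a fixed fine lattice of
// physical offsets, radius search_factor * dta, with exact distance-term
// pruning only (no subdivision heuristics).
// [[Rcpp::export]]
NumericVector cpp_gamma_dense(NumericVector ref, IntegerVector rdim,
                              NumericVector rspc, NumericVector rorg,
                              NumericVector ev, IntegerVector edim,
                              NumericVector espc, NumericVector eorg,
                              double dd_frac, double dta_mm, bool local,
                              double threshold_frac, double search_factor,
                              double lattice_mm) {
  int rnx = rdim[0], rny = rdim[1], rnz = rdim[2];
  int enx = edim[0], eny = edim[1], enz = edim[2];
  const double *rv = REAL(ref), *evp = REAL(ev);
  double eo[3] = {eorg[0], eorg[1], eorg[2]};
  double es[3] = {espc[0], espc[1], espc[2]};
  size_t nref = (size_t)rnx * rny * rnz;
  double refmax = 0;
  for (size_t i = 0; i < nref; i++) refmax = std::max(refmax, rv[i]);
  double thresh = threshold_frac * refmax;
  double dta2 = dta_mm * dta_mm;
  std::vector<Offset> offs = lattice_offsets(lattice_mm, search_factor * dta_mm);
  NumericVector out(nref);
  size_t idx = 0;
  for (int k = 0; k < rnz; k++) {
    double pz = rorg[2] + k * rspc[2];
    for (int j = 0; j < rny; j++) {
      double py = rorg[1] + j * rspc[1];
      for (int i = 0; i < rnx; i++, idx++) {
        double dref = rv[idx];
        if (dref < thresh || (local && dref <= 0)) {
          out[idx] = NA_REAL;
          continue;
        }
        double delta = dd_frac * (local ? dref : refmax);
        double dd2 = delta * delta;
        double px = rorg[0] + i * rspc[0];
        double best = R_PosInf;
        for (const Offset &o : offs) {
          if (o.r2 / dta2 >= best) break;
          bool inside;
          double x = (px + o.dx - eo[0]) / es[0];
          double y = (py + o.dy - eo[1]) / es[1];
          double z = (pz + o.dz - eo[2]) / es[2];
          double de = tri3(evp, enx, eny, enz, x, y, z, inside);
          if (!inside) continue;
          double dd = de - dref;
          double g2 = o.r2 / dta2 + dd * dd / dd2;
          if (g2 < best) best = g2;
        }
        out[idx] = R_FINITE(best) ? std::sqrt(best) : R_PosInf;
      }
    }
  }
  return out;
}
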