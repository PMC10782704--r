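#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All builders take a discretised level array (1..ng inside the mask, 0
// outside) in R column-major order. Directions follow the 13 unique 3-D
// angles at Chebyshev distance 1.

static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},  {1, 1, 0},   {1, -1, 0},
    {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},  {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline size_t vidx(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// Symmetric grey-level co-occurrence counts, one ng x ng slab per direction.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lv = INTEGER(lev);
  NumericVector out((size_t)ng * ng * 13);
  for (int d = 0; d < 13; d++) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *P = REAL(out) + (size_t)d * ng * ng;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int a = lv[vidx(i, j, k, nx, ny)];
          if (a == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
            continue;
          int b = lv[vidx(i2, j2, k2, nx, ny)];
          if (b == 0) continue;
          P[(a - 1) + (size_t)ng * (b - 1)] += 1.0;
          P[(b - 1) + (size_t)ng * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Grey-level run-length counts, ng x max_run per direction.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lv = INTEGER(lev);
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out((size_t)ng * maxlen * 13);
  for (int d = 0; d < 13; d++) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *P = REAL(out) + (size_t)d * ng * maxlen;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int a = lv[vidx(i, j, k, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor along direction is absent or different
          int ip = i - dx, jp = j - dy, kp = k - dz;
          bool start = (ip < 0 || jp < 0 || kp < 0 || ip >= nx || jp >= ny ||
                        kp >= nz || lv[vidx(ip, jp, kp, nx, ny)] != a);
          if (!start) continue;
          int len = 1;
          int in = i + dx, jn = j + dy, kn = k + dz;
          while (in >= 0 && jn >= 0 && kn >= 0 && in < nx && jn < ny &&
                 kn < nz && lv[vidx(in, jn, kn, nx, ny)] == a) {
            len++;
            in += dx;
            jn += dy;
            kn += dz;
          }
          P[(a - 1) + (size_t)ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Grey-level size-zone counts (26-connected components per level).
// Returns a matrix with columns (level, zone_size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lv = INTEGER(lev);
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; s++) {
    if (seen[s] || lv[s] == 0) continue;
    int a = lv[s];
    int count = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      count++;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
              continue;
            size_t v2 = vidx(i2, j2, k2, nx, ny);
            if (!seen[v2] && lv[v2] == a) {
              seen[v2] = 1;
              stack.push_back(v2);
            }
          }
    }
    zl.push_back(a);
    zs.push_back(count);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); r++) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}

// Neighbouring grey-tone difference: per level i, n_i (voxel count having at
// least one in-mask neighbour) and s_i = sum |i - mean(26-neighbourhood)|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lv = INTEGER(lev);
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = lv[vidx(i, j, k, nx, ny)];
        if (a == 0) continue;
        double sum = 0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny ||
                  k2 >= nz)
                continue;
              int b = lv[vidx(i2, j2, k2, nx, ny)];
              if (b == 0) continue;
              sum += b;
              cnt++;
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}

// Grey-level dependence counts: P(i, j) where j - 1 is the number of
// 26-neighbours whose level differs from the centre by at most alpha.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dim, int ng,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lv = INTEGER(lev);
  NumericMatrix out(ng, 27); // dependence size 1..27
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = lv[vidx(i, j, k, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny ||
                  k2 >= nz)
                continue;
              int b = lv[vidx(i2, j2, k2, nx, ny)];
              if (b != 0 && std::abs(b - a) <= alpha) dep++;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}
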