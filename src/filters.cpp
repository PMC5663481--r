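#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Edge handling for all filters: reflection (pixel -1 maps to 0, n maps to n-1).
static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// 3x3 median filter of a numeric matrix.
// [[Rcpp::export(name = ".median2d")]]
NumericMatrix median2d(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = reflect(j + dj, nc);
        for (int di = -1; di <= 1; ++di) {
          w[k++] = x(reflect(i + di, nr), jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}

// 3x3x3 median filter of a 3D numeric array (dim = c(nx, ny, nz)).
// [[Rcpp::export(name = ".median3d")]]
NumericVector median3d(NumericVector x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(x.size());
  out.attr("dim") = dim;
  double w[27];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xx = 0; xx < nx; ++xx) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = reflect(z + dz, nz);
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = reflect(y + dy, ny);
            R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
            for (int dx = -1; dx <= 1; ++dx) {
              w[k++] = x[base + reflect(xx + dx, nx)];
            }
          }
        }
        std::nth_element(w, w + 13, w + 27);
        out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + xx] = w[13];
      }
    }
  }
  return out;
}

// 6-connected labeling of a 3D logical/integer array; labels 1..K in
// first-encounter order (x fastest, then y, then z).
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p - (R_xlen_t)z * nx * ny);
      int y = rem / nx, xx = rem % nx;
      for (int d = 0; d < 6; ++d) {
        int ax = xx + dx[d], ay = y + dy[d], az = z + dz[d];
        if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)az * nx * ny + (R_xlen_t)ay * nx + ax;
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("max") = next;
  return lab;
}
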