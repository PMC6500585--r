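#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by iterative flood fill.
// mask is a logical/integer array in R's column-major (z, y, x) layout;
// connectivity is 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> oz, oy, ox;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  const int nn = (int)oz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v % nz);
      int j = (int)((v / nz) % ny);
      int i = (int)(v / ((R_xlen_t)nz * ny));
      for (int t = 0; t < nn; ++t) {
        int k2 = k + oz[t], j2 = j + oy[t], i2 = i + ox[t];
        if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny || i2 < 0 || i2 >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)i2 * nz * ny + (R_xlen_t)j2 * nz + k2;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
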