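// 3D connected-component labelling under 6/18/26-connectivity (voxel
// topology; anisotropic spacing deliberately ignored). Components are
// numbered in scan order (linear array index, x fastest), so component 1
// contains the first foreground voxel encountered — the R side uses this
// for deterministic tie-breaking between equal-sized components.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<int> sizes;
  int nextLabel = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++nextLabel;
    int sz = 0;
    stack.clear();
    stack.push_back(start);
    labels[start] = nextLabel;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      ++sz;
      const int x = v % nx;
      const int y = (v / nx) % ny;
      const int z = v / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < offx.size(); ++k) {
        const int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[u] && labels[u] == 0) {
          labels[u] = nextLabel;
          stack.push_back(u);
        }
      }
    }
    sizes.push_back(sz);
  }

  labels.attr("dim") = dims;
  return List::create(Named("labels") = labels,
                      Named("sizes") = wrap(sizes));
}
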