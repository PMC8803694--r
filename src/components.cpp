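#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3-D connected-component labelling restricted to a mask, where two voxels
// join the same component only if they carry the same value. Passing a
// constant `values` vector reduces this to ordinary binary labelling; passing
// grey levels yields the zones of a grey-level size-zone matrix.
//
// `mask` and `values` are in R's column-major array order for dimensions
// `dim` (length 3). Connectivity is 26 (default) or 6. Labels start at 1 in
// first-encounter (scan) order; background stays 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector values,
                               IntegerVector dim, int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n || values.size() != n)
    stop("mask/values length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets in (dx, dy, dz)
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    const int val = values[start];
    labels[start] = ++next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] && labels[nb] == 0 && values[nb] == val) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
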