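#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling for binary 2D/3D grids.
// full = true  -> 8-connectivity (2D) / 26-connectivity (3D)
// full = false -> 4-connectivity (2D) /  6-connectivity (3D)
// Returns an integer vector of the same length; background voxels get 0,
// components get labels 1..K in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector x, IntegerVector dims, bool full) {
  int nd = dims.size();
  if (nd != 2 && nd != 3) stop("dims must have length 2 or 3");
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("length(x) does not match prod(dims)");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = (nd == 3 ? -1 : 0); dz <= (nd == 3 ? 1 : 0); ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!full && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx;
      int cx = rem % nx;
      for (size_t k = 0; k < dxs.size(); ++k) {
        int px = cx + dxs[k], py = cy + dys[k], pz = cz + dzs[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
        R_xlen_t j = (R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px;
        if (x[j] == TRUE && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Per-ray occupied-voxel counts: project a 3D binary grid along one axis
// (1 = x, 2 = y, 3 = z), returning the count matrix for the remaining axes.
// [[Rcpp::export]]
IntegerMatrix cpp_project_counts(LogicalVector x, IntegerVector dims, int axis) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)x.size() != (R_xlen_t)nx * ny * nz) stop("length mismatch");
  int n1, n2;
  if (axis == 1)      { n1 = ny; n2 = nz; }
  else if (axis == 2) { n1 = nx; n2 = nz; }
  else if (axis == 3) { n1 = nx; n2 = ny; }
  else stop("axis must be 1, 2 or 3");
  IntegerMatrix out(n1, n2);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (x[idx] == TRUE) {
          if (axis == 1) out(j, k) += 1;
          else if (axis == 2) out(i, k) += 1;
          else out(i, j) += 1;
        }
      }
  return out;
}
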