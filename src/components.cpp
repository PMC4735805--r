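#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary 2D/3D array by flood fill.
// connectivity: 4 or 8 (2D), 6 or 26 (3D). Labels are 1..n in scan order
// of the first-encountered voxel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  int nd = dims.size();
  int nr = dims[0], nc = dims[1], nz = (nd == 3) ? dims[2] : 1;
  if (nd == 2 && connectivity != 4 && connectivity != 8)
    stop("2D connectivity must be 4 or 8");
  if (nd == 3 && connectivity != 6 && connectivity != 26)
    stop("3D connectivity must be 6 or 26");

  std::vector<std::array<int, 3>> offs;
  bool diag = (connectivity == 8 || connectivity == 26);
  for (int dz = -1; dz <= 1; ++dz) {
    if (nd == 2 && dz != 0) continue;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0 && dz == 0) continue;
        int nn = std::abs(dr) + std::abs(dc) + std::abs(dz);
        if (!diag && nn > 1) continue;
        offs.push_back({dr, dc, dz});
      }
    }
  }

  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur / ((R_xlen_t)nr * nc);
      int rem = cur % ((R_xlen_t)nr * nc);
      int c = rem / nr, r = rem % nr;
      for (size_t k = 0; k < offs.size(); ++k) {
        int rr = r + offs[k][0], cc = c + offs[k][1], zz = z + offs[k][2];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || zz < 0 || zz >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * nr * nc + (R_xlen_t)cc * nr + rr;
        if (mask[idx] != 0 && labels[idx] == 0) {
          labels[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}
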