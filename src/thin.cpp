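#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D curve skeletonization by distance-ordered homotopic thinning.
// A voxel may be deleted only if it is "simple" (deletion preserves both
// object and background topology; Bertrand/Malandain characterization with
// 26-connectivity for the object, 6-connectivity for the background) and not
// a curve endpoint (exactly one 26-neighbour). Border voxels are processed
// in increasing order of a priority field (the distance transform), so the
// skeleton settles on the medial line.

namespace {

inline int lidx(int z, int y, int x) { return z + 3 * (y + 3 * x); } // local 3x3x3

// object components (26-conn) among the 26 non-center cells must equal 1
// background 6-components within the 18-neighbourhood touching a face
// neighbour of the center must equal 1
bool is_simple(const bool nb[27]) {
  // --- object 26-components ---
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] >= 0) continue;
    int sp = 0;
    stack[sp++] = i;
    comp[i] = ncomp;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int z = cz + dz, y = cy + dy, x = cx + dx;
            if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
            int j = lidx(z, y, x);
            if (j == 13 || !nb[j] || comp[j] >= 0) continue;
            comp[j] = ncomp;
            stack[sp++] = j;
          }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;

  // --- background 6-components in N18 adjacent to center ---
  // N18: Chebyshev distance 1 and Manhattan distance <= 2 from center.
  bool in18[27];
  for (int z = 0; z < 3; ++z)
    for (int y = 0; y < 3; ++y)
      for (int x = 0; x < 3; ++x) {
        int md = std::abs(z - 1) + std::abs(y - 1) + std::abs(x - 1);
        in18[lidx(z, y, x)] = (md >= 1 && md <= 2);
      }
  int bcomp[27];
  for (int i = 0; i < 27; ++i) bcomp[i] = -1;
  int nb6 = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || bcomp[i] >= 0) continue;
    bool touches_face = false;
    int sp = 0;
    stack[sp++] = i;
    bcomp[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      if (std::abs(cz - 1) + std::abs(cy - 1) + std::abs(cx - 1) == 1)
        touches_face = true;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int z = cz + d6[k][0], y = cy + d6[k][1], x = cx + d6[k][2];
        if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
        int j = lidx(z, y, x);
        if (!in18[j] || nb[j] || bcomp[j] >= 0) continue;
        bcomp[j] = 1;
        stack[sp++] = j;
      }
    }
    if (touches_face) ++nb6;
  }
  return nb6 == 1;
}

} // namespace

// `anchors` (same shape as mask, or length 0 for none) marks voxels that
// may never be deleted: lobe-tip anchors force branches to survive the
// retraction, in the spirit of tube-penalized centreline trees.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, NumericVector priority,
                       LogicalVector anchors) {
  IntegerVector dim = mask.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> M((size_t)N);
  for (R_xlen_t i = 0; i < N; ++i) M[i] = mask[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> char {
    if (z < 0 || z >= n1 || y < 0 || y >= n2 || x < 0 || x >= n3) return 0;
    return M[z + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x)];
  };
  auto fill_nb = [&](int z, int y, int x, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[lidx(dz + 1, dy + 1, dx + 1)] = at(z + dz, y + dy, x + dx);
  };
  auto n26 = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  };
  auto is_border = [&](int z, int y, int x) {
    return !at(z + 1, y, x) || !at(z - 1, y, x) || !at(z, y + 1, x) ||
           !at(z, y - 1, x) || !at(z, y, x + 1) || !at(z, y, x - 1);
  };

  bool changed = true;
  std::vector<std::pair<double, R_xlen_t> > cand;
  while (changed) {
    changed = false;
    cand.clear();
    for (int x = 0; x < n3; ++x)
      for (int y = 0; y < n2; ++y)
        for (int z = 0; z < n1; ++z) {
          R_xlen_t i = z + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x);
          if (M[i] && is_border(z, y, x))
            cand.push_back(std::make_pair(priority[i], i));
        }
    std::sort(cand.begin(), cand.end());
    bool nb[27];
    const bool hasAnchors = anchors.size() == mask.size();
    for (size_t k = 0; k < cand.size(); ++k) {
      R_xlen_t i = cand[k].second;
      if (!M[i]) continue;
      if (hasAnchors && anchors[i]) continue;
      int z = (int)(i % n1);
      int y = (int)((i / n1) % n2);
      int x = (int)(i / ((R_xlen_t)n1 * n2));
      if (!is_border(z, y, x)) continue;
      fill_nb(z, y, x, nb);
      int nn = n26(nb);
      if (nn <= 1) continue;        // endpoint or isolated: keep
      if (!is_simple(nb)) continue; // would change topology
      M[i] = 0;
      changed = true;
    }
  }

  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = M[i] != 0;
  out.attr("dim") = dim;
  return out;
}
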