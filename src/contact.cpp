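#include <Rcpp.h>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Cell-cell contact enumeration on a labeled volume.
// A contact face is a shared face between 6-adjacent voxels carrying two
// different non-background labels; its physical area depends on orientation
// (face normal along z -> sy*sx, etc.). Faces of one label pair are grouped
// into patches: two faces belong to the same patch when their voxels are
// 26-adjacent on both sides of the interface.

namespace {

struct Face {
  int za, ya, xa; // voxel on the smaller-label side
  int zb, yb, xb; // voxel on the larger-label side
};

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

} // namespace

// [[Rcpp::export]]
DataFrame cpp_contact_areas(IntegerVector labels, NumericVector spacing,
                            int background) {
  IntegerVector dim = labels.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double farea[3] = {s2 * s3, s1 * s3, s1 * s2}; // normal along z,y,x

  typedef std::pair<int, int> PairKey;
  std::map<PairKey, std::vector<Face> > groups;
  std::map<PairKey, double> areas;

  auto lab = [&](int z, int y, int x) -> int {
    return labels[z + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x)];
  };
  auto add_face = [&](int ax, int z, int y, int x, int z2, int y2, int x2) {
    int la = lab(z, y, x), lb = lab(z2, y2, x2);
    if (la == background || lb == background || la == lb) return;
    Face f;
    if (la < lb) { f.za = z; f.ya = y; f.xa = x; f.zb = z2; f.yb = y2; f.xb = x2; }
    else { std::swap(la, lb); f.za = z2; f.ya = y2; f.xa = x2; f.zb = z; f.yb = y; f.xb = x; }
    PairKey k(la, lb);
    groups[k].push_back(f);
    areas[k] += farea[ax];
  };

  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y)
      for (int z = 0; z < n1; ++z) {
        if (z + 1 < n1) add_face(0, z, y, x, z + 1, y, x);
        if (y + 1 < n2) add_face(1, z, y, x, z, y + 1, x);
        if (x + 1 < n3) add_face(2, z, y, x, z, y, x + 1);
      }

  std::vector<int> la_out, lb_out, np_out;
  std::vector<double> a_out;
  for (std::map<PairKey, std::vector<Face> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    std::vector<Face>& fs = it->second;
    int nf = (int)fs.size();
    UF uf(nf);
    // spatial hash on the a-side voxel
    std::unordered_map<long long, std::vector<int> > h;
    for (int i = 0; i < nf; ++i) {
      long long key = fs[i].za + (long long)n1 * (fs[i].ya + (long long)n2 * fs[i].xa);
      h[key].push_back(i);
    }
    for (int i = 0; i < nf; ++i) {
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int z = fs[i].za + dz, y = fs[i].ya + dy, x = fs[i].xa + dx;
            if (z < 0 || z >= n1 || y < 0 || y >= n2 || x < 0 || x >= n3) continue;
            long long key = z + (long long)n1 * (y + (long long)n2 * x);
            std::unordered_map<long long, std::vector<int> >::iterator hit = h.find(key);
            if (hit == h.end()) continue;
            const std::vector<int>& cands = hit->second;
            for (size_t c = 0; c < cands.size(); ++c) {
              int j = cands[c];
              if (j == i) continue;
              if (std::abs(fs[i].zb - fs[j].zb) <= 1 &&
                  std::abs(fs[i].yb - fs[j].yb) <= 1 &&
                  std::abs(fs[i].xb - fs[j].xb) <= 1)
                uf.unite(i, j);
            }
          }
    }
    int np = 0;
    for (int i = 0; i < nf; ++i) if (uf.find(i) == i) ++np;
    la_out.push_back(it->first.first);
    lb_out.push_back(it->first.second);
    a_out.push_back(areas[it->first]);
    np_out.push_back(np);
  }

  return DataFrame::create(_["label_a"] = wrap(la_out), _["label_b"] = wrap(lb_out),
                           _["area"] = wrap(a_out), _["n_patches"] = wrap(np_out));
}
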