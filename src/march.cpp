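#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// subdivision of each grid cell. The Kuhn split is face-consistent across
// neighbouring cells, so welding shared edge-vertices yields a watertight,
// consistently oriented triangle mesh for any iso-surface that does not
// touch the array border (callers pad the field with a background layer).
// Grid point (z,y,x) sits at physical position ((x+.5)sx, (y+.5)sy, (z+.5)sz);
// vertices are returned in (x,y,z) µm, faces as 1-based index triples.

namespace {

struct MTVert { double x, y, z; };

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, double level, NumericVector spacing) {
  IntegerVector dim = field.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2]; // (z,y,x)
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const R_xlen_t NP = (R_xlen_t)n1 * n2 * n3;

  auto gid = [&](int z, int y, int x) -> R_xlen_t {
    return z + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x);
  };

  std::vector<MTVert> verts;
  std::vector<int> tris; // triples of 0-based vertex ids
  std::unordered_map<long long, int> edge_vertex;

  auto edge_vert = [&](R_xlen_t ga, R_xlen_t gb) -> int {
    long long key;
    if (ga < gb) key = (long long)ga * NP + gb; else key = (long long)gb * NP + ga;
    std::unordered_map<long long, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = field[ga], fb = field[gb];
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int za = (int)(ga % n1), ya = (int)((ga / n1) % n2), xa = (int)(ga / ((R_xlen_t)n1 * n2));
    int zb = (int)(gb % n1), yb = (int)((gb / n1) % n2), xb = (int)(gb / ((R_xlen_t)n1 * n2));
    MTVert v;
    v.x = ((xa + t * (xb - xa)) + 0.5) * s3;
    v.y = ((ya + t * (yb - ya)) + 0.5) * s2;
    v.z = ((za + t * (zb - za)) + 0.5) * s1;
    int id = (int)verts.size();
    verts.push_back(v);
    edge_vertex[key] = id;
    return id;
  };

  // physical position of a grid point, for orientation only
  auto ppos = [&](R_xlen_t g, double* p) {
    int z = (int)(g % n1), y = (int)((g / n1) % n2), x = (int)(g / ((R_xlen_t)n1 * n2));
    p[0] = (x + 0.5) * s3; p[1] = (y + 0.5) * s2; p[2] = (z + 0.5) * s1;
  };

  auto emit_tri = [&](int v0, int v1, int v2, const double* din) {
    // din: direction pointing from inside to outside; orient normal with it
    const MTVert& a = verts[v0];
    const MTVert& b = verts[v1];
    const MTVert& c = verts[v2];
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double wx = c.x - a.x, wy = c.y - a.y, wz = c.z - a.z;
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    if (nx * din[0] + ny * din[1] + nz * din[2] < 0) std::swap(v1, v2);
    tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
  };

  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  // axes: 0 -> z, 1 -> y, 2 -> x offsets
  for (int x = 0; x + 1 < n3; ++x)
    for (int y = 0; y + 1 < n2; ++y)
      for (int z = 0; z + 1 < n1; ++z)
        for (int pm = 0; pm < 6; ++pm) {
          int off[4][3]; // (dz,dy,dx) of the 4 tet corners
          off[0][0] = 0; off[0][1] = 0; off[0][2] = 0;
          for (int k = 1; k <= 3; ++k) {
            off[k][0] = off[k - 1][0]; off[k][1] = off[k - 1][1]; off[k][2] = off[k - 1][2];
            int ax = perms[pm][k - 1];
            if (ax == 0) off[k][0] = 1; else if (ax == 1) off[k][1] = 1; else off[k][2] = 1;
          }
          R_xlen_t g[4];
          bool in[4];
          for (int k = 0; k < 4; ++k) {
            g[k] = gid(z + off[k][0], y + off[k][1], x + off[k][2]);
            in[k] = field[g[k]] >= level;
          }
          int nin = in[0] + in[1] + in[2] + in[3];
          if (nin == 0 || nin == 4) continue;

          // inside -> outside direction for orientation
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0}, p[3];
          for (int k = 0; k < 4; ++k) {
            ppos(g[k], p);
            if (in[k]) { ci[0] += p[0]; ci[1] += p[1]; ci[2] += p[2]; }
            else { co[0] += p[0]; co[1] += p[1]; co[2] += p[2]; }
          }
          double din[3] = {co[0] / (4 - nin) - ci[0] / nin,
                           co[1] / (4 - nin) - ci[1] / nin,
                           co[2] / (4 - nin) - ci[2] / nin};

          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int k = 0; k < 4; ++k)
              if (in[k] == (nin == 1)) lone = k;
            int vv[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != lone) vv[m++] = edge_vert(g[lone], g[k]);
            emit_tri(vv[0], vv[1], vv[2], din);
          } else { // nin == 2: quad split into two triangles
            int ia = -1, ib = -1, oa = -1, ob = -1;
            for (int k = 0; k < 4; ++k) {
              if (in[k]) { if (ia < 0) ia = k; else ib = k; }
              else { if (oa < 0) oa = k; else ob = k; }
            }
            int q0 = edge_vert(g[ia], g[oa]);
            int q1 = edge_vert(g[ia], g[ob]);
            int q2 = edge_vert(g[ib], g[ob]);
            int q3 = edge_vert(g[ib], g[oa]);
            emit_tri(q0, q1, q2, din);
            emit_tri(q0, q2, q3, din);
          }
        }

  int nv = (int)verts.size(), nf = (int)tris.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = verts[i].x; V(i, 1) = verts[i].y; V(i, 2) = verts[i].z; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = tris[3 * i] + 1; Fm(i, 1) = tris[3 * i + 1] + 1; Fm(i, 2) = tris[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
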