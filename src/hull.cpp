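#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
#include <utility>
using namespace Rcpp;

// Incremental 3D convex hull, returning the enclosed volume (signed
// tetrahedra against an interior point over outward-oriented facets).
// Inputs need not be in general position: points within eps of a facet
// plane are treated as interior. Every constructed hull is audited
// (closed oriented manifold, all points inside); an attempt that fails
// the audit is retried with a different deterministic insertion order
// and, if needed, a coarser eps. Only if every attempt fails is an
// error raised — a returned volume is always a verified hull.

namespace {

struct V3 { double x, y, z; };
inline V3 sub(const V3& a, const V3& b) { V3 r = {a.x - b.x, a.y - b.y, a.z - b.z}; return r; }
inline V3 cross(const V3& a, const V3& b) {
  V3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Facet {
  int a, b, c;
  V3 n;       // unit outward normal
  double d;   // plane offset: dot(n, x) = d
  bool alive;
};

// one construction attempt; returns hull volume or NaN if the audit fails
double hull_attempt(const std::vector<V3>& P, double diag, double eps,
                    unsigned long long shuffle_state, bool& degenerate_input) {
  const int n = (int)P.size();
  degenerate_input = false;

  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x || (P[i].x == P[i0].x && (P[i].y < P[i0].y ||
        (P[i].y == P[i0].y && P[i].z < P[i0].z)))) i0 = i;
  int i1 = -1; double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dd = norm(sub(P[i], P[i0]));
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= eps) { degenerate_input = true; return NA_REAL; }
  V3 u = sub(P[i1], P[i0]);
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dd = norm(cross(sub(P[i], P[i0]), u));
    if (dd > best) { best = dd; i2 = i; }
  }
  if (best <= eps * norm(u)) { degenerate_input = true; return NA_REAL; }
  V3 nrm = cross(u, sub(P[i2], P[i0]));
  double nn = norm(nrm);
  nrm.x /= nn; nrm.y /= nn; nrm.z /= nn;
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dd = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best <= eps) { degenerate_input = true; return NA_REAL; }

  V3 o = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
          (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
          (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Facet> F;
  F.reserve(512);
  auto add_facet = [&](int a, int b, int c) {
    Facet f;
    V3 nf = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double l = norm(nf);
    if (l <= 0) return;
    nf.x /= l; nf.y /= l; nf.z /= l;
    if (dot(nf, sub(P[a], o)) < 0) { std::swap(b, c); nf.x = -nf.x; nf.y = -nf.y; nf.z = -nf.z; }
    f.a = a; f.b = b; f.c = c; f.n = nf; f.d = dot(nf, P[a]); f.alive = true;
    F.push_back(f);
  };
  add_facet(i0, i1, i2);
  add_facet(i0, i1, i3);
  add_facet(i0, i2, i3);
  add_facet(i1, i2, i3);

  // deterministic xorshift shuffle of the insertion order
  std::vector<int> order;
  order.reserve(n);
  for (int p = 0; p < n; ++p)
    if (p != i0 && p != i1 && p != i2 && p != i3) order.push_back(p);
  unsigned long long state = shuffle_state;
  for (size_t k = order.size(); k > 1; --k) {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    std::swap(order[k - 1], order[state % k]);
  }

  std::vector<int> visible;
  for (size_t pi = 0; pi < order.size(); ++pi) {
    int p = order[pi];
    visible.clear();
    for (size_t f = 0; f < F.size(); ++f)
      if (F[f].alive && dot(F[f].n, P[p]) - F[f].d > eps) visible.push_back((int)f);
    if (visible.empty()) continue;
    std::set<std::pair<int,int> > edges;
    for (size_t k = 0; k < visible.size(); ++k) {
      const Facet& f = F[visible[k]];
      edges.insert(std::make_pair(f.a, f.b));
      edges.insert(std::make_pair(f.b, f.c));
      edges.insert(std::make_pair(f.c, f.a));
    }
    for (size_t k = 0; k < visible.size(); ++k) F[visible[k]].alive = false;
    for (std::set<std::pair<int,int> >::iterator it = edges.begin(); it != edges.end(); ++it)
      if (edges.find(std::make_pair(it->second, it->first)) == edges.end())
        add_facet(it->first, it->second, p);
  }

  // audit: closed oriented surface, every point inside (within tolerance)
  std::set<std::pair<int,int> > alive_edges;
  for (size_t f = 0; f < F.size(); ++f) {
    if (!F[f].alive) continue;
    alive_edges.insert(std::make_pair(F[f].a, F[f].b));
    alive_edges.insert(std::make_pair(F[f].b, F[f].c));
    alive_edges.insert(std::make_pair(F[f].c, F[f].a));
  }
  for (std::set<std::pair<int,int> >::iterator it = alive_edges.begin();
       it != alive_edges.end(); ++it)
    if (alive_edges.find(std::make_pair(it->second, it->first)) == alive_edges.end())
      return NA_REAL;
  double worst = 0.0;
  for (size_t f = 0; f < F.size(); ++f) {
    if (!F[f].alive) continue;
    for (int p = 0; p < n; ++p) {
      double d = dot(F[f].n, P[p]) - F[f].d;
      if (d > worst) worst = d;
    }
  }
  if (worst > 20.0 * eps) return NA_REAL;

  double vol = 0.0;
  for (size_t f = 0; f < F.size(); ++f) {
    if (!F[f].alive) continue;
    V3 a = sub(P[F[f].a], o), b = sub(P[F[f].b], o), c = sub(P[F[f].c], o);
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return vol;
}

} // namespace

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<V3> P((size_t)n);
  for (int i = 0; i < n; ++i) { P[i].x = pts(i, 0); P[i].y = pts(i, 1); P[i].z = pts(i, 2); }

  V3 lo = P[0], hi = P[0];
  for (int i = 1; i < n; ++i) {
    lo.x = std::min(lo.x, P[i].x); lo.y = std::min(lo.y, P[i].y); lo.z = std::min(lo.z, P[i].z);
    hi.x = std::max(hi.x, P[i].x); hi.y = std::max(hi.y, P[i].y); hi.z = std::max(hi.z, P[i].z);
  }
  double diag = norm(sub(hi, lo));
  if (diag <= 0) stop("degenerate point set (all points identical)");

  const double eps_scales[3] = {1e-9, 1e-8, 1e-7};
  const unsigned long long seeds[3] = {88172645463325252ULL,
                                       1181783497276652981ULL,
                                       4292484099903637661ULL};
  for (int es = 0; es < 3; ++es) {
    for (int sd = 0; sd < 3; ++sd) {
      bool degen = false;
      double v = hull_attempt(P, diag, eps_scales[es] * diag, seeds[sd], degen);
      if (degen)
        stop("degenerate point set (collinear or coplanar points)");
      if (R_finite(v)) return v;
    }
  }
  stop("convex hull construction failed; input too degenerate");
}
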