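#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Local thickness in the largest-inscribed-sphere sense (Hildebrand &
// Ruegsegger): thickness(v) = diameter of the largest ball that contains v
// and fits inside the mask. Computed by painting, for every foreground voxel
// w with inscribed-ball radius r(w) (the distance transform), the value 2*r(w)
// over all voxels within r(w) of w, keeping the per-voxel maximum. Radii are
// physical (anisotropic spacing respected).
// [[Rcpp::export]]
NumericVector cpp_thickness_paint(LogicalVector mask, NumericVector radii,
                                  NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;

  std::vector<std::pair<double, R_xlen_t> > order;
  for (R_xlen_t i = 0; i < N; ++i)
    if (mask[i]) order.push_back(std::make_pair(-radii[i], i));
  std::sort(order.begin(), order.end()); // descending radius

  NumericVector th(N);
  const double tol = 1e-9;
  for (size_t k = 0; k < order.size(); ++k) {
    R_xlen_t i = order[k].second;
    double r = radii[i];
    if (r <= 0) continue;
    double d = 2.0 * r;
    int z = (int)(i % n1), y = (int)((i / n1) % n2), x = (int)(i / ((R_xlen_t)n1 * n2));
    int rz = (int)std::floor(r / s1 + tol);
    int ry = (int)std::floor(r / s2 + tol);
    int rx = (int)std::floor(r / s3 + tol);
    for (int dx = -rx; dx <= rx; ++dx) {
      int xx = x + dx;
      if (xx < 0 || xx >= n3) continue;
      double px = dx * s3;
      for (int dy = -ry; dy <= ry; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= n2) continue;
        double py = dy * s2;
        if (px * px + py * py > r * r + tol) continue;
        for (int dz = -rz; dz <= rz; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= n1) continue;
          double pz = dz * s1;
          if (px * px + py * py + pz * pz > r * r + tol) continue;
          R_xlen_t j = zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
          if (mask[j] && th[j] < d) th[j] = d;
        }
      }
    }
  }
  th.attr("dim") = dim;
  return th;
}
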