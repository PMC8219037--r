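#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D mask, 6- or 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back(dz); offs.push_back(dy); offs.push_back(dx);
      }
  int no = (int)offs.size() / 3;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int z = (int)(i % n1), y = (int)((i / n1) % n2), x = (int)(i / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < no; ++k) {
        int zz = z + offs[3 * k], yy = y + offs[3 * k + 1], xx = x + offs[3 * k + 2];
        if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
        R_xlen_t j = zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
        if (mask[j] && lab[j] == 0) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
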