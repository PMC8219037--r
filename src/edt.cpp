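#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transform, one axis, weighted sample spacing w.
// Felzenszwalb & Huttenlocher lower-envelope-of-parabolas scan.
// BIG stands in for +Inf so the envelope arithmetic stays finite.
static const double BIG = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;                      // new parabola dominates everywhere
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < w * q) ++k;
    int p = v[k];
    double diff = w * (q - p);
    d[q] = diff * diff + f[p];
  }
}

// Anisotropic Euclidean distance transform on a 3D mask (dim = (n1,n2,n3),
// R column-major). Returns, for every foreground voxel, the distance from its
// center to the nearest background voxel center; 0 on background. Voxels of a
// mask with no background at all come back as a value >= sqrt(BIG)/2.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> D((size_t)N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int q = 0; q < n1; ++q) f[q] = D[base + q];
      dt1d(f, d, v, z, n1, s1);
      for (int q = 0; q < n1; ++q) D[base + q] = d[q];
    }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * i3;
      for (int q = 0; q < n2; ++q) f[q] = D[base + (R_xlen_t)n1 * q];
      dt1d(f, d, v, z, n2, s2);
      for (int q = 0; q < n2; ++q) D[base + (R_xlen_t)n1 * q] = d[q];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t st3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
      for (int q = 0; q < n3; ++q) f[q] = D[base + st3 * q];
      dt1d(f, d, v, z, n3, s3);
      for (int q = 0; q < n3; ++q) D[base + st3 * q] = d[q];
    }

  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing of a 3D field in voxel units (same sigma per
// axis), zero padding outside the array. Used to lift a binary mask to a
// smooth indicator before iso-surfacing.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector field, double sigma) {
  IntegerVector dim = field.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (sigma <= 0) return clone(field);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& k : ker) k /= s;

  std::vector<double> A((size_t)N), B((size_t)N);
  for (R_xlen_t i = 0; i < N; ++i) A[i] = field[i];

  const int n[3] = {n1, n2, n3};
  const R_xlen_t stride[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
  for (int ax = 0; ax < 3; ++ax) {
    const R_xlen_t st = stride[ax];
    const int len = n[ax];
    // iterate over all lines along ax
    for (int i3 = 0; i3 < (ax == 2 ? 1 : n3); ++i3)
      for (int i2 = 0; i2 < (ax == 1 ? 1 : n2); ++i2)
        for (int i1 = 0; i1 < (ax == 0 ? 1 : n1); ++i1) {
          R_xlen_t base = i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
          for (int q = 0; q < len; ++q) {
            double acc = 0.0;
            int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
            for (int j = lo; j <= hi; ++j)
              acc += ker[j - q + r] * A[base + st * j];
            B[base + st * q] = acc;
          }
        }
    std::swap(A, B);
  }
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = A[i];
  out.attr("dim") = dim;
  return out;
}
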