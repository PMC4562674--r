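// Performance kernels of the spatial integrator: axis-wise tensor
// contraction (the cosine-basis transforms), the mirror-ghost Laplacian and
// the flux-form chemotaxis operator.  Index conventions match R arrays
// (column-major, 1-based axes at the interface).

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Apply the square matrices M1, M2, M3 along the three spatial axes of a
// stack of fields u (dim (K1, K2, K3, ns) or (K1, K2, K3)), entirely via
// BLAS dgemm on the column-major layout:
//   axis 1: one product M1 * U with U = (K1, K2*K3*ns);
//   axis 2: per (K3*ns) slab, (K1, K2) * M2^T;
//   axis 3: per field, (K1*K2, K3) * M3^T.
// [[Rcpp::export]]
NumericVector axes_transform(NumericVector u, NumericMatrix M1,
                             NumericMatrix M2, NumericMatrix M3) {
  IntegerVector dims = u.attr("dim");
  int nd = dims.size();
  if (nd != 3 && nd != 4) stop("expected a 3- or 4-d array");
  int K1 = dims[0], K2 = dims[1], K3 = dims[2];
  int ns = (nd == 4) ? dims[3] : 1;
  if (M1.nrow() != K1 || M1.ncol() != K1 ||
      M2.nrow() != K2 || M2.ncol() != K2 ||
      M3.nrow() != K3 || M3.ncol() != K3) stop("matrix/axis size mismatch");
  NumericVector buf1(u.size()), buf2(u.size());
  const double one = 1.0, zero = 0.0;
  // axis 1
  int rest = K2 * K3 * ns;
  F77_CALL(dgemm)("N", "N", &K1, &rest, &K1, &one, M1.begin(), &K1,
                  u.begin(), &K1, &zero, buf1.begin(), &K1 FCONE FCONE);
  // axis 2: slabs of K1 x K2, result = slab * M2^T
  int nslab = K3 * ns;
  R_xlen_t slab = (R_xlen_t)K1 * K2;
  for (int t = 0; t < nslab; ++t)
    F77_CALL(dgemm)("N", "T", &K1, &K2, &K2, &one, buf1.begin() + t * slab,
                    &K1, M2.begin(), &K2, &zero, buf2.begin() + t * slab,
                    &K1 FCONE FCONE);
  // axis 3: per field, (K1*K2, K3) * M3^T
  int K12 = K1 * K2;
  R_xlen_t fld = (R_xlen_t)K12 * K3;
  for (int s = 0; s < ns; ++s)
    F77_CALL(dgemm)("N", "T", &K12, &K3, &K3, &one, buf2.begin() + s * fld,
                    &K12, M3.begin(), &K3, &zero, buf1.begin() + s * fld,
                    &K12 FCONE FCONE);
  buf1.attr("dim") = dims;
  return buf1;
}

static inline int mirror_up(int i, int K) { return (i + 1 < K) ? i + 1 : K - 1; }
static inline int mirror_dn(int i) { return (i > 0) ? i - 1 : 0; }

// coef * sum_axis K_axis^2 (u_+ + u_- - 2 u) with mirror ghost cells.
// [[Rcpp::export]]
NumericVector laplacian_kernel(NumericVector u, IntegerVector K, double coef) {
  int K1 = K[0], K2 = K[1], K3 = K[2];
  double c1 = (double)K1 * K1, c2 = (double)K2 * K2, c3 = (double)K3 * K3;
  NumericVector out(u.size());
  out.attr("dim") = u.attr("dim");
  const double* x = u.begin();
  double* y = out.begin();
  R_xlen_t s2 = K1, s3 = (R_xlen_t)K1 * K2;
  for (int k = 0; k < K3; ++k)
    for (int j = 0; j < K2; ++j)
      for (int i = 0; i < K1; ++i) {
        R_xlen_t id = i + s2 * j + s3 * k;
        double v = x[id];
        double acc =
          c1 * (x[mirror_up(i, K1) + s2 * j + s3 * k] +
                x[mirror_dn(i) + s2 * j + s3 * k] - 2.0 * v) +
          c2 * (x[i + s2 * mirror_up(j, K2) + s3 * k] +
                x[i + s2 * mirror_dn(j) + s3 * k] - 2.0 * v) +
          c3 * (x[i + s2 * j + s3 * mirror_up(k, K3)] +
                x[i + s2 * j + s3 * mirror_dn(k)] - 2.0 * v);
        y[id] = coef * acc;
      }
  return out;
}

// Flux-form -div(M1 chi grad P): face flux chi * M1_face * dP/dx with the
// donor (upwind) face density, or the arithmetic face average (central).
// Boundary faces carry no flux, so the cell sum is exactly zero.
// [[Rcpp::export]]
NumericVector chemotaxis_kernel(NumericVector M1, NumericVector P,
                                IntegerVector K, double chi, bool upwind) {
  int K1 = K[0], K2 = K[1], K3 = K[2];
  NumericVector out(M1.size());
  out.attr("dim") = M1.attr("dim");
  const double* m = M1.begin();
  const double* p = P.begin();
  double* y = out.begin();
  R_xlen_t s2 = K1, s3 = (R_xlen_t)K1 * K2;
  int Ks[3] = {K1, K2, K3};
  R_xlen_t strides[3] = {1, s2, s3};
  for (int ax = 0; ax < 3; ++ax) {
    double kk = (double)Ks[ax];
    R_xlen_t st = strides[ax];
    for (int k = 0; k < K3; ++k)
      for (int j = 0; j < K2; ++j)
        for (int i = 0; i < K1; ++i) {
          int idx_ax = (ax == 0) ? i : (ax == 1 ? j : k);
          if (idx_ax >= Ks[ax] - 1) continue;  // faces between cells only
          R_xlen_t a = i + s2 * j + s3 * k;
          R_xlen_t b = a + st;
          double vel = chi * (p[b] - p[a]) * kk;
          double mf;
          if (upwind) mf = (vel > 0) ? m[a] : m[b];
          else mf = 0.5 * (m[a] + m[b]);
          double flux = vel * mf;
          y[a] -= flux * kk;
          y[b] += flux * kk;
        }
  }
  return out;
}
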