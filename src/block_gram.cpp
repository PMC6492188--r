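#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Apply the block-diagonal aliasing-set Gram operator.
//
// C:       complex array of per-set coil Gram matrices, dim R x R x G
//          (column-major; C[p + R*q + R*R*g] = sum_c conj(S_c(v_p)) S_c(v_q))
// members: integer matrix R x G of 1-based voxel indices of each set
// X:       complex matrix nvox x nd
//
// Returns Y with Y[v_p, j] = sum_q C[p, q, g] X[v_q, j] for the set g
// containing voxel v_p.  Every voxel belongs to exactly one set.  The
// set loop is outermost so each small Gram block stays cached while it
// is applied across all volumes.
// [[Rcpp::export(name = ".block_gram_apply")]]
ComplexMatrix block_gram_apply_cpp(ComplexVector C, IntegerMatrix members,
                                   ComplexMatrix X) {
  const int R = members.nrow();
  const int G = members.ncol();
  const int nv = X.nrow();
  const int nd = X.ncol();
  if ((R_xlen_t)R * R * G != C.size())
    stop("C has wrong length for the given member table");
  ComplexMatrix Y(nv, nd);
  const std::complex<double>* cp =
      reinterpret_cast<const std::complex<double>*>(&C[0]);
  const std::complex<double>* xp =
      reinterpret_cast<const std::complex<double>*>(&X[0]);
  std::complex<double>* yp = reinterpret_cast<std::complex<double>*>(&Y[0]);
  const int* mp = &members[0];
  std::vector<std::complex<double> > xbuf((size_t)R * nd);
  std::vector<std::complex<double> > ybuf((size_t)R * nd);
  for (int g = 0; g < G; ++g) {
    const int* mg = mp + (R_xlen_t)g * R;
    const std::complex<double>* cg = cp + (R_xlen_t)g * R * R;
    // gather the set's rows: xbuf[q + R*j] = X[mg[q]-1, j]
    for (int q = 0; q < R; ++q) {
      const std::complex<double>* xrow = xp + (mg[q] - 1);
      for (int j = 0; j < nd; ++j)
        xbuf[(size_t)R * j + q] = xrow[(size_t)j * nv];
    }
    // small matrix product: ybuf(:, j) = C_g * xbuf(:, j)
    for (int j = 0; j < nd; ++j) {
      const std::complex<double>* xc = &xbuf[(size_t)R * j];
      std::complex<double>* yc = &ybuf[(size_t)R * j];
      for (int p = 0; p < R; ++p) {
        double ar = 0.0, ai = 0.0;
        for (int q = 0; q < R; ++q) {
          const std::complex<double> c = cg[p + R * q];
          const std::complex<double> x = xc[q];
          ar += c.real() * x.real() - c.imag() * x.imag();
          ai += c.real() * x.imag() + c.imag() * x.real();
        }
        yc[p] = std::complex<double>(ar, ai);
      }
    }
    // scatter back
    for (int q = 0; q < R; ++q) {
      std::complex<double>* yrow = yp + (mg[q] - 1);
      for (int j = 0; j < nd; ++j)
        yrow[(size_t)j * nv] = ybuf[(size_t)R * j + q];
    }
  }
  return Y;
}
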