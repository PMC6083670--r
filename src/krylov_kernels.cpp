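// Complex sparse kernels for the Helmholtz Krylov solvers.
//
// Matrices arrive as the three CSC arrays of a Matrix::dgCMatrix pattern with
// a complex value vector. All system matrices here are complex symmetric
// (FEM/FD discretizations), so the CSC arrays are simultaneously a valid CSR
// representation; the kernels below index them as CSR rows.

#include <Rcpp.h>
#include <complex>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline cplx* cptr(ComplexVector& v) {
  return reinterpret_cast<cplx*>(COMPLEX(v));
}
static inline const cplx* cptr(const ComplexVector& v) {
  return reinterpret_cast<const cplx*>(COMPLEX(const_cast<ComplexVector&>(v)));
}

// y = A x for CSR (p: row pointers, j: column indices, both 0-based)
// [[Rcpp::export]]
ComplexVector csr_matvec(IntegerVector p, IntegerVector j, ComplexVector x,
                         ComplexVector v) {
  const int n = p.size() - 1;
  ComplexVector out(n);
  const cplx* xa = cptr(x);
  const cplx* va = cptr(v);
  cplx* ya = cptr(out);
  for (int r = 0; r < n; ++r) {
    cplx acc(0.0, 0.0);
    for (int q = p[r]; q < p[r + 1]; ++q) acc += xa[q] * va[j[q]];
    ya[r] = acc;
  }
  return out;
}

// In-place ILU(0) on a CSR matrix with sorted column indices per row.
// Returns list(x = combined LU values, diag = 0-based diagonal positions).
// L is unit lower triangular (multipliers stored below the diagonal),
// U occupies the diagonal and above.
// [[Rcpp::export]]
List ilu0_factor(IntegerVector p, IntegerVector j, ComplexVector x) {
  const int n = p.size() - 1;
  ComplexVector lu = clone(x);
  cplx* a = cptr(lu);
  IntegerVector diag(n, -1);
  std::vector<int> work(n, -1);

  for (int r = 0; r < n; ++r) {
    for (int q = p[r]; q < p[r + 1]; ++q) work[j[q]] = q;
    for (int q = p[r]; q < p[r + 1]; ++q) {
      const int k = j[q];
      if (k >= r) break;                     // past the strict lower part
      const int dk = diag[k];
      const cplx piv = a[dk];
      if (std::abs(piv) == 0.0)
        stop("ILU(0) breakdown: zero pivot in row %d", k + 1);
      const cplx lik = a[q] / piv;
      a[q] = lik;
      for (int q2 = dk + 1; q2 < p[k + 1]; ++q2) {
        const int pos = work[j[q2]];
        if (pos >= 0) a[pos] -= lik * a[q2];
      }
    }
    const int dr = work[r];
    if (dr < 0) stop("ILU(0): missing diagonal entry in row %d", r + 1);
    diag[r] = dr;
    if (std::abs(a[dr]) == 0.0)
      stop("ILU(0) breakdown: zero pivot in row %d", r + 1);
    for (int q = p[r]; q < p[r + 1]; ++q) work[j[q]] = -1;
  }
  return List::create(_["x"] = lu, _["diag"] = diag);
}

// Solve (L U) z = b given the combined ILU(0) factors.
// [[Rcpp::export]]
ComplexVector ilu0_solve(IntegerVector p, IntegerVector j, ComplexVector lu,
                         IntegerVector diag, ComplexVector b) {
  const int n = p.size() - 1;
  ComplexVector out = clone(b);
  const cplx* a = cptr(lu);
  cplx* z = cptr(out);
  for (int r = 0; r < n; ++r) {             // forward: L z = b, unit diagonal
    cplx acc = z[r];
    for (int q = p[r]; q < diag[r]; ++q) acc -= a[q] * z[j[q]];
    z[r] = acc;
  }
  for (int r = n - 1; r >= 0; --r) {        // backward: U z = z
    cplx acc = z[r];
    for (int q = diag[r] + 1; q < p[r + 1]; ++q) acc -= a[q] * z[j[q]];
    z[r] = acc / a[diag[r]];
  }
  return out;
}
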