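#include <Rcpp.h>

// LAPACK banded complex solver; not declared in R_ext/Lapack.h but
// exported by every full LAPACK implementation R links against
extern "C" void zgbsv_(const int *n, const int *kl, const int *ku,
                       const int *nrhs, Rcomplex *ab, const int *ldab,
                       int *ipiv, Rcomplex *b, const int *ldb, int *info);

// Solve A x = b for a complex matrix in LAPACK band storage.
// `ab` must have ldab = 2*kl + ku + 1 rows with A(i,j) stored at
// ab(kl + ku + 1 + i - j, j) (1-based); the leading kl rows are workspace.
// [[Rcpp::export]]
Rcpp::ComplexVector banded_solve_cpp(Rcpp::ComplexMatrix ab,
                                     Rcpp::ComplexVector b,
                                     int kl, int ku) {
  int n = ab.ncol();
  int ldab = ab.nrow();
  if (ldab != 2 * kl + ku + 1)
    Rcpp::stop("band storage must have 2*kl + ku + 1 rows");
  if (b.size() != n) Rcpp::stop("right-hand side length mismatch");
  int nrhs = 1, info = 0;
  std::vector<int> ipiv(n);
  Rcpp::ComplexMatrix ab_work = Rcpp::clone(ab);
  Rcpp::ComplexVector x = Rcpp::clone(b);
  zgbsv_(&n, &kl, &ku, &nrhs, ab_work.begin(), &ldab, ipiv.data(),
         x.begin(), &n, &info);
  if (info != 0)
    Rcpp::stop("zgbsv failed with info = %d (singular system?)", info);
  return x;
}
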