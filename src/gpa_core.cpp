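// Hot loop of the generalized Procrustes fit: iterative rotation of all
// (already centered, unit-centroid-size) configurations onto the running
// consensus. Pre-scaling, sliding and everything else stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-squares rotation of X onto C (both centered); proper rotation
// enforced by sign-flipping the smallest singular axis.
static mat opt_rot(const mat& X, const mat& C) {
  mat M = X.t() * C;
  mat U, V;
  vec d;
  svd(U, d, V, M);
  mat R = U * V.t();
  if (det(R) < 0) {
    U.col(U.n_cols - 1) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// [[Rcpp::export]]
Rcpp::List cpp_gpa_fit(arma::cube X, arma::mat C, double tol, int max_iter) {
  const uword n = X.n_slices;
  const double np = static_cast<double>(X.n_rows) * X.n_cols;
  if (C.n_elem == 0) C = X.slice(0);
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    for (uword i = 0; i < n; ++i)
      X.slice(i) = X.slice(i) * opt_rot(X.slice(i), C);
    mat Cnew = mean(X, 2);
    Cnew.each_row() -= mean(Cnew, 0);
    Cnew /= norm(Cnew, "fro");
    double delta = std::sqrt(accu(square(Cnew - C)) / np);
    C = Cnew;
    ++it;
    if (delta < tol) { converged = true; break; }
  }
  return Rcpp::List::create(Rcpp::Named("coords") = X,
                            Rcpp::Named("consensus") = C,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
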