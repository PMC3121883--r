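// Pairwise two-selection RMSD matrix: for each ordered pair (i, j) the
// mobile conformation j is Kabsch-fit onto i over the fit atoms, then the
// RMSD is taken over the measure atoms.  The fitted RMSD is invariant to
// swapping the roles of i and j, so only the upper triangle is computed
// and mirrored.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void kabsch_transform(const mat& P, const mat& Q, mat& R, rowvec& t) {
  // P: mobile fit atoms (k x 3), Q: reference fit atoms (k x 3)
  rowvec cp = mean(P, 0), cq = mean(Q, 0);
  mat Pc = P.each_row() - cp;
  mat Qc = Q.each_row() - cq;
  mat H = Pc.t() * Qc;           // 3x3
  mat U, V; vec s;
  svd(U, s, V, H);
  double d = det(V * U.t());
  mat D = eye<mat>(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cq - cp * R.t();
}

// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& coords,
                            const arma::uvec& fit_idx,
                            const arma::uvec& rmsd_idx) {
  const uword n = coords.n_slices;
  mat out(n, n, fill::zeros);
  std::vector<mat> fit(n), meas(n);
  for (uword i = 0; i < n; ++i) {
    mat sl = coords.slice(i);
    fit[i] = sl.rows(fit_idx);
    meas[i] = sl.rows(rmsd_idx);
  }
  mat R; rowvec t;
  for (uword i = 0; i + 1 < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      kabsch_transform(fit[j], fit[i], R, t);
      mat moved = meas[j] * R.t();
      moved.each_row() += t;
      mat diff = moved - meas[i];
      double msd = accu(diff % diff) / meas[i].n_rows;
      double r = std::sqrt(msd);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
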