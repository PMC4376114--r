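// Point-based Bellman backup for the Perseus solver.
//
// For a belief b and the current alpha-vector set A (one vector per row),
// computes for every action a the backed-up value
//   rb + gamma * sum_z max_i  b' T_a diag(O_z) alpha_i
// and returns the action-tagged vector maximizing it (ties to the lowest
// action index). Tp holds one S x S' transition matrix per action slice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_point_backup(const arma::vec& belief, const arma::mat& A,
                            const arma::cube& Tp, const arma::mat& O,
                            const arma::vec& R, double gamma) {
  const uword S = belief.n_elem;
  const uword Z = O.n_cols;
  const uword nA = Tp.n_slices;
  const mat At = A.t();  // S x n_alpha
  const double rb = dot(belief, R);

  double best_val = -datum::inf;
  int best_a = -1;
  vec best_vec(S, fill::zeros);

  for (uword a = 0; a < nA; ++a) {
    const mat& Ta = Tp.slice(a);       // S x S'
    const vec u = Ta.t() * belief;     // S'
    const mat Sc = (A.each_row() % u.t()) * O;  // n_alpha x Z
    uvec j(Z);
    double tot = 0.0;
    for (uword z = 0; z < Z; ++z) {
      uword idx;
      const double m = Sc.col(z).max(idx);
      j(z) = idx;
      tot += m;
    }
    const double val = rb + gamma * tot;
    if (best_a < 0 || val > best_val) {
      vec C(S, fill::zeros);           // C(s') = sum_z O(s',z) alpha*_z(s')
      for (uword z = 0; z < Z; ++z) {
        C += O.col(z) % At.col(j(z));
      }
      best_vec = R + gamma * (Ta * C);
      best_val = val;
      best_a = static_cast<int>(a);
    }
  }
  return Rcpp::List::create(Rcpp::Named("vector") = best_vec,
                            Rcpp::Named("action") = best_a,
                            Rcpp::Named("value") = best_val);
}
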