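// Local-diabatization electronic propagator.
//
// Over one nuclear step the diagonal-representation states at t and t+dt
// are connected by the Loewdin-orthonormalized overlap T.  The new-step
// Hamiltonian expressed in the old basis is Z = T diag(E1) T^H; the
// coefficients are advanced through n_sub midpoint exponentials of the
// linearly interpolated Hamiltonian and finally rotated into the new
// basis:  c(t+dt) = T^H * prod_k exp(-i H(s_k) dtau / hbar) * c(t).
//
// Energies in eV, times in fs, hbar in eV fs.  The returned matrix is the
// full-step propagator R with c_new = R c_old; R is unitary to machine
// precision (each factor is an exact exponential of a Hermitian matrix).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double HBAR_EV_FS = 0.6582119569509066;

// [[Rcpp::export]]
arma::cx_mat ld_propagator_cpp(const arma::vec& E0,
                               const arma::cx_mat& T,
                               const arma::vec& E1,
                               double dt_fs,
                               int n_sub) {
  const arma::uword D = E0.n_elem;
  if (T.n_rows != D || T.n_cols != D || E1.n_elem != D)
    Rcpp::stop("dimension mismatch in ld_propagator");
  if (n_sub < 1) Rcpp::stop("n_sub must be >= 1");

  const arma::cx_mat H0 = arma::diagmat(arma::cx_vec(E0, arma::vec(D, arma::fill::zeros)));
  const arma::cx_mat Z = T * arma::diagmat(arma::cx_vec(E1, arma::vec(D, arma::fill::zeros))) * T.t();

  const double dtau = dt_fs / n_sub;
  arma::cx_mat U = arma::cx_mat(D, D, arma::fill::eye);
  arma::vec eval;
  arma::cx_mat evec;
  for (int k = 0; k < n_sub; ++k) {
    const double s = (k + 0.5) / n_sub;
    arma::cx_mat H = (1.0 - s) * H0 + s * Z;
    H = 0.5 * (H + H.t());  // symmetrize round-off
    if (!arma::eig_sym(eval, evec, H))
      Rcpp::stop("eigendecomposition failed in electronic substep");
    const arma::cx_vec ph = arma::exp(arma::cx_double(0.0, -dtau / HBAR_EV_FS) * arma::conv_to<arma::cx_vec>::from(eval));
    U = evec * arma::diagmat(ph) * evec.t() * U;
  }
  return T.t() * U;
}
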