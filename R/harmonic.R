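#' Harmonic reference oscillator
#'
#' Bundles the ground-state equilibrium geometry, atomic masses, harmonic
#' frequencies and the Cartesian-to-normal-mode transformation matrix that
#' together define the shared harmonic ground-state surface
#' \eqn{V_0(Q) = \sum_i \hbar\omega_i Q_i^2 / 2} and the dimensionless
#' mass-frequency-scaled coordinates \eqn{Q_i}.
#'
#' The columns of \code{K} are the usual mass-weighted normal-mode vectors
#' and must be mutually orthonormal (checked to 1e-8).
#'
#' @param coords numeric matrix (n_atoms x 3), equilibrium geometry in
#'   Angstrom.
#' @param masses numeric vector of atomic masses (amu), length n_atoms.
#' @param omega numeric vector of harmonic frequencies (cm^-1), all > 0.
#' @param K numeric matrix (3*n_atoms x F) of mass-weighted normal-mode
#'   vectors (dimensionless), orthonormal columns.
#' @return an object of class \code{harmonic_reference}.
#' @export
harmonic_reference <- function(coords, masses, omega, K) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n_atoms x 3 matrix")
  n_atoms <- nrow(coords)
  masses <- as.numeric(masses)
  if (length(masses) != n_atoms) stop("masses must have one entry per atom")
  if (any(masses <= 0)) stop("masses must be positive")
  omega <- as.numeric(omega)
  if (any(omega <= 0)) stop("all frequencies must be positive")
  K <- as.matrix(K)
  nf <- length(omega)
  if (nrow(K) != 3L * n_atoms || ncol(K) != nf)
    stop("K must be (3*n_atoms) x F with F = length(omega)")
  if (nf > 3L * n_atoms) stop("mode count exceeds 3*n_atoms")
  dev <- max(abs(crossprod(K) - diag(nf)))
  if (dev > 1e-8)
    stop(sprintf("normal-mode vectors not orthonormal (deviation %.3g)", dev))
  structure(
    list(coords = coords, masses = masses, omega = omega, K = K,
         n_atoms = n_atoms, n_modes = nf),
    class = "harmonic_reference")
}

#' @export
print.harmonic_reference <- function(x, ...) {
  cat(sprintf(
    "<harmonic_reference> %d atoms, %d modes, omega %.1f..%.1f cm^-1\n",
    x$n_atoms, x$n_modes, min(x$omega), max(x$omega)))
  invisible(x)
}

#' Transform a Cartesian geometry to normal-mode coordinates
#'
#' Computes the dimensionless mass-frequency-scaled coordinates
#' \eqn{Q_i = \sqrt{\omega_i/\hbar}\sum_\alpha K_{\alpha i}\sqrt{M_\alpha}
#' (r_\alpha - r^{ref}_\alpha)} (atomic units internally).
#'
#' @param reference a \code{harmonic_reference}.
#' @param r geometry, either an n_atoms x 3 matrix or a length 3*n_atoms
#'   vector, in Angstrom, same atom order as the reference.
#' @return numeric vector Q of length F (dimensionless).
#' @export
to_normal_coordinates <- function(reference, r) {
  stopifnot(inherits(reference, "harmonic_reference"))
  r <- as.numeric(t(as.matrix(r)))
  r0 <- as.numeric(t(reference$coords))
  if (length(r) != length(r0))
    stop("geometry has wrong atom count/order for this reference")
  dr_au <- (r - r0) * lvc_units$bohr_per_angstrom
  m_au <- rep(reference$masses * lvc_units$me_per_amu, each = 3L)
  w_au <- ev2au(cm12ev(reference$omega))
  sqrt(w_au) * as.numeric(crossprod(reference$K, sqrt(m_au) * dr_au))
}

#' Inverse of \code{to_normal_coordinates}
#'
#' Maps mode coordinates back to the Cartesian geometry
#' \eqn{r = r^{ref} + M^{-1/2} K \, \omega^{-1/2} Q}. Components of a
#' displacement outside the mode subspace are not representable and are
#' dropped by the forward transform.
#'
#' @param reference a \code{harmonic_reference}.
#' @param Q numeric vector of mode coordinates (dimensionless), length F.
#' @return n_atoms x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
from_normal_coordinates <- function(reference, Q) {
  stopifnot(inherits(reference, "harmonic_reference"))
  Q <- as.numeric(Q)
  if (length(Q) != reference$n_modes) stop("Q must have length F")
  w_au <- ev2au(cm12ev(reference$omega))
  m_au <- rep(reference$masses * lvc_units$me_per_amu, each = 3L)
  dr_au <- as.numeric(reference$K %*% (Q / sqrt(w_au))) / sqrt(m_au)
  r0 <- as.numeric(t(reference$coords))
  matrix(r0 + dr_au / lvc_units$bohr_per_angstrom, ncol = 3L, byrow = TRUE)
}

## hbar*omega per mode in eV (the natural energy quantum of each mode)
mode_quantum_ev <- function(reference) cm12ev(reference$omega)
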