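## Representation transforms: diabatic -> MCH (spin-free adiabatic) ->
## diagonal (spin-orbit-including) basis, plus gradients, nonadiabatic
## couplings and time overlaps.

## Fix eigenvector phases (and, through U_ref, continuity) so that
## diag(Re(U_ref^H U)) >= 0.  U_ref defaults to the identity.
phase_fix <- function(U, U_ref = NULL) {
  if (is.null(U_ref)) {
    d <- diag(U)
  } else {
    d <- diag(Conj(t(U_ref)) %*% U)
  }
  if (is.complex(U)) {
    ph <- ifelse(Mod(d) > 0, Conj(d) / Mod(d), 1 + 0i)
    U * rep(ph, each = nrow(U))
  } else {
    s <- ifelse(Re(d) >= 0, 1, -1)
    U * rep(s, each = nrow(U))
  }
}

#' Adiabatize the spin-free diabatic potential matrix
#'
#' Diagonalizes the diabatic potential matrix per multiplicity block,
#' \eqn{V = U E^{MCH} U^\dagger}, giving the spin-free MCH energies
#' (ascending within each block) and the block-orthogonal
#' diabatic-to-MCH transform U.  Eigenvector phases are fixed so the
#' diagonal of \eqn{U_{ref}^\dagger U} is non-negative (continuity with a
#' previous step, or with the identity at the reference geometry), and
#' degenerate ties are resolved by the lexicographic order of the dominant
#' diabatic component.
#'
#' @param pot result of \code{\link{evaluate_potential}} (or any list with
#'   element \code{V}).
#' @param basis the \code{electronic_basis} describing the block structure.
#' @param U_prev optional previous-step transform for phase continuity.
#' @return list with \code{E_mch} (eV, length n_sf) and \code{U}
#'   (n_sf x n_sf, block-diagonal, orthogonal).
#' @export
adiabatize <- function(pot, basis, U_prev = NULL) {
  V <- pot$V
  n_sf <- basis$n_sf
  U <- matrix(0, n_sf, n_sf)
  E <- numeric(n_sf)
  for (m in unique(basis$multiplicity)) {
    idx <- which(basis$multiplicity == m)
    eg <- eigen(V[idx, idx, drop = FALSE], symmetric = TRUE)
    ord <- order(eg$values)
    vals <- eg$values[ord]
    vecs <- eg$vectors[, ord, drop = FALSE]
    ## tie-break within numerically degenerate clusters: order by the row
    ## index of the dominant diabatic component
    j <- 1L
    while (j <= length(vals)) {
      k <- j
      while (k < length(vals) && vals[k + 1L] - vals[j] < 1e-12) k <- k + 1L
      if (k > j) {
        sub <- j:k
        dom <- apply(abs(vecs[, sub, drop = FALSE]), 2L, which.max)
        vecs[, sub] <- vecs[, sub[order(dom)], drop = FALSE]
        vals[sub] <- vals[sub][order(dom)]
      }
      j <- k + 1L
    }
    E[idx] <- vals
    U[idx, idx] <- vecs
  }
  U <- phase_fix(U, U_prev)
  list(E_mch = E, U = U)
}

#' Transform SOC and dipole matrices into the MCH basis
#'
#' Applies \eqn{A^{MCH} = \tilde U^\dagger A \tilde U}, where for the SOC
#' matrix \eqn{\tilde U} is the diabatic-to-MCH transform replicated over
#' the spin-expansion blocks, and for the (spin-free) dipole matrices it is
#' U itself.  Hermiticity is preserved exactly up to round-off.
#'
#' @param U spin-free diabatic-to-MCH transform (n_sf x n_sf).
#' @param basis the \code{electronic_basis}.
#' @param soc optional D x D Hermitian diabatic SOC matrix (eV).
#' @param dipoles optional list of three symmetric n_sf x n_sf matrices.
#' @return list with \code{soc_mch} and/or \code{dipoles_mch}.
#' @export
transform_properties <- function(U, basis, soc = NULL, dipoles = NULL) {
  out <- list()
  if (!is.null(soc)) {
    if (max(abs(soc - Conj(t(soc)))) > 1e-10)
      stop("SOC matrix is not Hermitian")
    Ux <- spin_expand_transform(basis, U)
    out$soc_mch <- Conj(t(Ux)) %*% soc %*% Ux
  }
  if (!is.null(dipoles)) {
    out$dipoles_mch <- lapply(dipoles, function(m) {
      if (max(abs(m - t(m))) > 1e-10) stop("dipole matrix is not symmetric")
      crossprod(U, m) %*% U
    })
  }
  out
}

## Replicate the spin-free transform over the spin-expansion blocks
## (block-diagonal in MS; triplet sub-block repeated three times).
spin_expand_transform <- function(basis, U) {
  ns <- basis$n_singlets; nt <- basis$n_triplets
  D <- basis$dim
  Ux <- matrix(0, D, D)
  s_idx <- which(basis$multiplicity == 1L)
  t_idx <- which(basis$multiplicity == 3L)
  Ux[seq_len(ns), seq_len(ns)] <- U[s_idx, s_idx]
  if (nt > 0L) {
    Ut <- U[t_idx, t_idx, drop = FALSE]
    for (b in 0:2) {
      rows <- ns + b * nt + seq_len(nt)
      Ux[rows, rows] <- Ut
    }
  }
  Ux
}

#' Build and diagonalize the SOC-including Hamiltonian
#'
#' Assembles \eqn{H = diag(E^{MCH}) + SOC^{MCH}} over the spin-expanded
#' basis and computes its complex eigendecomposition (the "diagonal"
#' representation in which surface hops occur), with ascending eigenvalues
#' and the same phase convention as \code{\link{adiabatize}}.
#'
#' @param E_mch spin-free MCH energies (eV, length n_sf).
#' @param soc_mch D x D Hermitian SOC matrix in the MCH basis (eV).
#' @param basis the \code{electronic_basis}.
#' @param U_prev optional previous-step \code{U_diag} for phase continuity.
#' @return list with \code{H} (D x D complex), \code{E_diag} (ascending)
#'   and \code{U_diag} (D x D unitary).
#' @export
build_diagonal <- function(E_mch, soc_mch, basis, U_prev = NULL) {
  map <- spin_expansion_map(basis)
  H <- soc_mch + 0i
  diag(H) <- diag(H) + E_mch[map]
  herm <- max(abs(H - Conj(t(H))))
  if (herm > 1e-8) stop("total Hamiltonian not Hermitian")
  eg <- eigen((H + Conj(t(H))) / 2)  # symmetrize round-off; Hermitian solver
  ord <- order(eg$values)
  U_diag <- phase_fix(eg$vectors[, ord, drop = FALSE] + 0i, U_prev)
  list(H = H, E_diag = eg$values[ord], U_diag = U_diag)
}

#' MCH gradients and nonadiabatic coupling vectors
#'
#' Hellmann-Feynman gradients of the MCH states,
#' \eqn{g^{(n)}_i = (U^\dagger \partial V/\partial Q_i \, U)_{nn}}, and
#' first-order nonadiabatic couplings
#' \eqn{NAC^{(n,m)}_i = (U^\dagger \partial V/\partial Q_i \,
#' U)_{nm} / (E_m - E_n)}, in the mode basis and back-transformed to
#' Cartesian coordinates via the normal-mode matrix and masses.
#' Near-degenerate pairs (gap below \code{floor_ev}) give unreliable NACs:
#' these are flagged and their magnitude capped at the value attained at
#' the degeneracy floor.
#'
#' @param adiab result of \code{\link{adiabatize}}.
#' @param pot result of \code{\link{evaluate_potential}} with derivatives.
#' @param model the \code{lvc_model} (for the Cartesian back-transform).
#' @param n state index (1-based, spin-free).
#' @param m optional second state for the NAC (\code{m != n}).
#' @param floor_ev degeneracy floor for the NAC denominator (eV).
#' @return list with \code{grad_modes} (eV per unit Q), \code{grad_cart}
#'   (eV per Angstrom, n_atoms x 3) and, when \code{m} is given,
#'   \code{nac_modes}, \code{nac_cart} (1/Angstrom) and \code{reliable}.
#' @export
mch_gradient_and_nac <- function(adiab, pot, model, n, m = NULL,
                                 floor_ev = 1e-8) {
  p <- model$parameters
  nf <- p$n_modes
  U <- adiab$U
  dV <- pot$dV
  if (is.null(dV)) stop("potential evaluation lacks derivatives")
  un <- U[, n]
  grad <- vapply(seq_len(nf), function(i) sum(un * (dV[, , i] %*% un)),
                 numeric(1))
  out <- list(grad_modes = grad,
              grad_cart = modes_to_cartesian(model$reference, grad,
                                             gradient = TRUE))
  if (!is.null(m)) {
    if (m == n) stop("NAC requires two distinct states")
    if (model$parameters$basis$multiplicity[n] !=
        model$parameters$basis$multiplicity[m])
      stop("NAC is defined within one multiplicity block")
    um <- U[, m]
    num <- vapply(seq_len(nf), function(i) sum(un * (dV[, , i] %*% um)),
                  numeric(1))
    gap <- adiab$E_mch[m] - adiab$E_mch[n]
    reliable <- abs(gap) > floor_ev
    denom <- if (reliable) gap else sign(gap + (gap == 0)) * floor_ev
    out$nac_modes <- num / denom
    out$nac_cart <- modes_to_cartesian(model$reference, out$nac_modes,
                                       gradient = TRUE)
    out$reliable <- reliable
  }
  out
}

## Back-transform a mode-basis covector (gradient-like, eV per unit Q or
## 1/Q) to Cartesian components: d/dr_alpha = sum_i (dQ_i/dr_alpha) d/dQ_i
## with dQ_i/dr_alpha = sqrt(omega_i) K_{alpha i} sqrt(M_alpha) (a.u.).
modes_to_cartesian <- function(reference, v_modes, gradient = TRUE) {
  w_au <- ev2au(cm12ev(reference$omega))
  m_au <- rep(reference$masses * lvc_units$me_per_amu, each = 3L)
  cart_au <- sqrt(m_au) * as.numeric(reference$K %*% (sqrt(w_au) * v_modes))
  ## value carried per unit Q stays in caller's units; convert per-bohr
  ## to per-Angstrom
  matrix(cart_au * lvc_units$bohr_per_angstrom, ncol = 3L, byrow = TRUE)
}

## Loewdin orthonormalization S -> S (S^H S)^(-1/2) via SVD.
loewdin <- function(S) {
  sv <- svd(S)
  if (min(sv$d) < 1e-10)
    stop("overlap matrix is rank deficient; cannot orthonormalize")
  sv$u %*% Conj(t(sv$v))
}

#' Time-overlap matrix between successive transforms
#'
#' Computes \eqn{S = U(t)^\dagger U(t+\Delta t)} (states expressed in the
#' common, time-independent diabatic basis), Loewdin-orthonormalizes it and
#' aligns column phases so the diagonal is real and non-negative.  This is
#' the overlap input of the local-diabatization electronic propagator.
#'
#' @param U_prev,U_curr transforms at t and t + dt (same dimensions); for
#'   the full dynamics these are the products \eqn{U_{expanded} U_{diag}}.
#' @param step optional step index used in error messages.
#' @param align_phases re-phase columns so the diagonal is real and
#'   non-negative.  The default (TRUE) suits standalone use, where the two
#'   transforms carry independent arbitrary phases.  Inside the propagation
#'   loop the phases of \code{U_curr} are already fixed by continuity with
#'   \code{U_prev}, and re-phasing against a near-zero overlap diagonal
#'   (states swapping order at a crossing) would inject arbitrary relative
#'   phases into the coefficients, so the propagator uses FALSE.
#' @return unitary overlap matrix S (to 1e-10).
#' @export
time_overlap <- function(U_prev, U_curr, step = NA, align_phases = TRUE) {
  if (!all(dim(U_prev) == dim(U_curr)))
    stop("overlap requires transforms of equal dimension")
  S0 <- Conj(t(U_prev)) %*% U_curr
  S <- tryCatch(loewdin(S0), error = function(e)
    stop(sprintf("time overlap at step %s: %s", step, conditionMessage(e))))
  if (align_phases) phase_fix(S) else S
}
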