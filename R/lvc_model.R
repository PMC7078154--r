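#' Linear vibronic coupling parameters
#'
#' Collects the diabatic LVC parameters: vertical shifts \eqn{\epsilon_n},
#' intrastate gradients \eqn{\kappa_i^{(n)}}, interstate couplings
#' \eqn{\lambda_i^{(n,m)}}, the spin-orbit coupling matrix over the
#' spin-expanded basis and the transition dipole matrices over the spin-free
#' states.  \eqn{\kappa} and \eqn{\lambda} connect only states of equal
#' multiplicity; the SOC matrix must be Hermitian.
#'
#' @param basis an \code{electronic_basis}.
#' @param epsilon numeric vector of vertical shifts (eV), length n_sf
#'   (ground state first, usually 0).
#' @param kappa numeric matrix (n_sf x F) of intrastate gradients
#'   (eV per unit Q); zero rows allowed.
#' @param lam numeric array (n_sf x n_sf x F) of interstate couplings
#'   (eV per unit Q), symmetric in the first two indices, zero across
#'   multiplicities.
#' @param soc complex Hermitian matrix (D x D) of spin-orbit couplings (eV)
#'   over the spin-expanded basis; defaults to zero.
#' @param dipoles list of three real symmetric (n_sf x n_sf) matrices
#'   (components x, y, z; atomic units); defaults to zero.
#' @param n_modes number of modes F (needed when kappa/lam are NULL).
#' @return object of class \code{lvc_parameters}.
#' @export
lvc_parameters <- function(basis, epsilon, kappa = NULL, lam = NULL,
                           soc = NULL, dipoles = NULL, n_modes = NULL) {
  stopifnot(inherits(basis, "electronic_basis"))
  n_sf <- basis$n_sf
  D <- basis$dim
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) != n_sf) stop("epsilon must have length n_sf")
  if (is.null(n_modes)) {
    n_modes <- if (!is.null(kappa)) ncol(kappa)
    else if (!is.null(lam)) dim(lam)[3] else stop("n_modes unknown")
  }
  n_modes <- as.integer(n_modes)
  if (is.null(kappa)) kappa <- matrix(0, n_sf, n_modes)
  kappa <- as.matrix(kappa)
  if (!all(dim(kappa) == c(n_sf, n_modes))) stop("kappa must be n_sf x F")
  if (is.null(lam)) lam <- array(0, c(n_sf, n_sf, n_modes))
  if (!all(dim(lam) == c(n_sf, n_sf, n_modes)))
    stop("lam must be n_sf x n_sf x F")
  if (is.null(soc)) soc <- matrix(0 + 0i, D, D)
  soc <- as.matrix(soc)
  storage.mode(soc) <- "complex"
  if (!all(dim(soc) == c(D, D))) stop("soc must be D x D over the spin basis")
  if (is.null(dipoles)) dipoles <- replicate(3, matrix(0, n_sf, n_sf),
                                             simplify = FALSE)
  if (length(dipoles) != 3L) stop("dipoles must have components x, y, z")
  dipoles <- lapply(dipoles, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n_sf, n_sf))) stop("dipole matrices must be n_sf x n_sf")
    m
  })
  names(dipoles) <- c("x", "y", "z")
  obj <- structure(
    list(basis = basis, epsilon = epsilon, kappa = kappa, lam = lam,
         soc = soc, dipoles = dipoles, n_modes = n_modes),
    class = "lvc_parameters")
  validate_lvc_parameters(obj)
  obj
}

#' Validate LVC parameter invariants
#'
#' Checks symmetry of \code{lam} in its state indices, the multiplicity
#' block structure of \code{kappa}/\code{lam}, Hermiticity of the SOC
#' matrix (1e-10) and symmetry of the dipole matrices.
#'
#' @param p an \code{lvc_parameters} object.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
validate_lvc_parameters <- function(p) {
  basis <- p$basis
  mult <- basis$multiplicity
  cross <- outer(mult, mult, "!=")
  for (i in seq_len(p$n_modes)) {
    L <- p$lam[, , i]
    if (max(abs(L - t(L))) > 1e-12)
      stop(sprintf("lambda slice for mode %d is not symmetric", i))
    if (any(abs(L[cross]) > 0))
      stop(sprintf("lambda couples different multiplicities (mode %d)", i))
  }
  herm <- max(abs(p$soc - Conj(t(p$soc))))
  if (herm > 1e-10)
    stop(sprintf("SOC matrix not Hermitian (deviation %.3g)", herm))
  for (cc in names(p$dipoles)) {
    m <- p$dipoles[[cc]]
    if (max(abs(m - t(m))) > 1e-10)
      stop(sprintf("dipole component %s not symmetric", cc))
  }
  invisible(TRUE)
}

#' @export
print.lvc_parameters <- function(x, ...) {
  cat(sprintf(
    "<lvc_parameters> %d singlets + %d triplets, %d modes, |SOC|max = %.4g eV\n",
    x$basis$n_singlets, x$basis$n_triplets, x$n_modes, max(Mod(x$soc))))
  invisible(x)
}

#' Assemble an LVC model
#'
#' Couples a \code{harmonic_reference} (coordinates, ground-state surface)
#' with \code{lvc_parameters} (diabatic potential matrix, SOC, dipoles) and
#' optionally a fragment charge-transfer number table.
#'
#' @param reference a \code{harmonic_reference}.
#' @param parameters an \code{lvc_parameters} with matching mode count.
#' @param ct_table optional \code{ct_number_table} over the same spin-free
#'   states.
#' @return object of class \code{lvc_model}.
#' @export
lvc_model <- function(reference, parameters, ct_table = NULL) {
  stopifnot(inherits(reference, "harmonic_reference"),
            inherits(parameters, "lvc_parameters"))
  if (reference$n_modes != parameters$n_modes)
    stop("reference and parameters disagree on the mode count")
  if (!is.null(ct_table)) {
    stopifnot(inherits(ct_table, "ct_number_table"))
    if (ct_table$n_states != parameters$basis$n_sf)
      stop("ct_table state count does not match the electronic basis")
  }
  structure(list(reference = reference, parameters = parameters,
                 ct_table = ct_table),
            class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  print(x$reference); print(x$parameters)
  if (!is.null(x$ct_table))
    cat(sprintf("  with CT table over fragments: %s\n",
                paste(x$ct_table$fragments, collapse = ", ")))
  invisible(x)
}

#' Evaluate the diabatic LVC potential matrix
#'
#' At mode coordinates Q computes \eqn{V = V_0 \mathbf{1} + W} with
#' \eqn{V_0 = \sum_i \hbar\omega_i Q_i^2/2},
#' \eqn{W_{nn} = \epsilon_n + \sum_i \kappa^{(n)}_i Q_i} and
#' \eqn{W_{nm} = \sum_i \lambda^{(n,m)}_i Q_i}, together with the exact
#' analytic mode derivatives \eqn{\partial V/\partial Q_i}.
#'
#' @param model an \code{lvc_model}.
#' @param Q numeric vector of mode coordinates (dimensionless), length F.
#' @param derivatives if \code{TRUE} include the per-mode derivative
#'   matrices (n_sf x n_sf x F).
#' @return list with elements \code{Q}, \code{V0} (eV), \code{V}
#'   (n_sf x n_sf, eV) and optionally \code{dV} (eV per unit Q).
#' @export
evaluate_potential <- function(model, Q, derivatives = TRUE) {
  stopifnot(inherits(model, "lvc_model"))
  p <- model$parameters
  Q <- as.numeric(Q)
  nf <- p$n_modes
  if (length(Q) != nf) stop("Q must have length F")
  n_sf <- p$basis$n_sf
  hw <- mode_quantum_ev(model$reference)   # hbar*omega_i in eV
  V0 <- sum(hw * Q^2) / 2
  ## W from the flattened lambda array: one matrix product over modes
  W <- matrix(matrix(p$lam, n_sf * n_sf, nf) %*% Q, n_sf, n_sf)
  diag(W) <- diag(W) + p$epsilon + as.numeric(p$kappa %*% Q)
  V <- W
  diag(V) <- diag(V) + V0
  out <- list(Q = Q, V0 = V0, V = V)
  if (derivatives) {
    dV <- p$lam
    for (i in seq_len(nf)) {
      d <- matrix(dV[, , i], n_sf, n_sf)
      diag(d) <- diag(d) + p$kappa[, i] + hw[i] * Q[i]
      dV[, , i] <- d
    }
    out$dV <- dV
  }
  out
}

#' Truncate an LVC model
#'
#' Removes low-frequency modes, drops listed electronic states and
#' optionally zeroes the spin-orbit couplings of the ground state, the
#' three cleanup operations used when deriving a production model from a
#' raw parametrization (low-frequency modes are strongly anharmonic in
#' reality and produce spuriously large \eqn{\lambda_i Q_i} terms; badly
#' mixed high-lying states carry unreliable couplings; DFT does not treat
#' the closed-shell ground state on the same footing as the response
#' states, so its SOCs can create artificial crossings).
#'
#' @param model an \code{lvc_model}.
#' @param omega_cut frequency cutoff (cm^-1); modes with
#'   \eqn{\omega < } \code{omega_cut} are deleted.
#' @param remove_states character vector of state labels to delete.
#' @param drop_s0_soc if \code{TRUE}, zero all SOC elements involving the
#'   ground state.
#' @return a truncated \code{lvc_model} satisfying all invariants.
#' @export
truncate_model <- function(model, omega_cut = 0, remove_states = NULL,
                           drop_s0_soc = FALSE) {
  stopifnot(inherits(model, "lvc_model"))
  if (omega_cut < 0) stop("omega_cut must be >= 0")
  ref <- model$reference
  p <- model$parameters
  basis <- p$basis

  keep_modes <- which(ref$omega >= omega_cut)
  if (length(keep_modes) == 0L) stop("omega_cut would remove every mode")

  if (!is.null(remove_states)) {
    unknown <- setdiff(remove_states, basis$labels)
    if (length(unknown))
      stop("unknown state labels: ", paste(unknown, collapse = ", "))
  }
  keep_states <- which(!(basis$labels %in% remove_states))
  if (!1L %in% keep_states) stop("cannot remove the ground state")
  keep_mult <- basis$multiplicity[keep_states]
  ns <- sum(keep_mult == 1L)
  nt <- sum(keep_mult == 3L)
  if (ns + nt < 2L && nt == 0L && ns < 2L && basis$n_sf > 1L)
    stop("truncation would remove all excited states")

  new_basis <- electronic_basis(ns, nt, labels = basis$labels[keep_states])

  ## spin-expanded index selection, preserving the MS-block layout
  old_map <- spin_expansion_map(basis)
  old_ms <- spin_expansion_ms(basis)
  ## singlets first, then triplet blocks ms = -1, 0, +1
  sing_idx <- which(old_map %in% keep_states[keep_mult == 1L] &
                    seq_along(old_map) <= basis$n_singlets)
  keep_spin <- sing_idx
  for (ms in c(-1L, 0L, 1L)) {
    idx <- which(old_map %in% keep_states[keep_mult == 3L] & old_ms == ms &
                 seq_along(old_map) > basis$n_singlets)
    keep_spin <- c(keep_spin, idx)
  }

  soc <- p$soc[keep_spin, keep_spin, drop = FALSE]
  if (drop_s0_soc) {
    soc[1L, ] <- 0 + 0i
    soc[, 1L] <- 0 + 0i
  }

  new_ref <- harmonic_reference(ref$coords, ref$masses,
                                ref$omega[keep_modes],
                                ref$K[, keep_modes, drop = FALSE])
  new_par <- lvc_parameters(
    new_basis,
    epsilon = p$epsilon[keep_states],
    kappa = p$kappa[keep_states, keep_modes, drop = FALSE],
    lam = p$lam[keep_states, keep_states, keep_modes, drop = FALSE],
    soc = soc,
    dipoles = lapply(p$dipoles, function(m)
      m[keep_states, keep_states, drop = FALSE]))

  ct <- model$ct_table
  if (!is.null(ct)) ct <- subset_ct_table(ct, keep_states)
  lvc_model(new_ref, new_par, ct)
}
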