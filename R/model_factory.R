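## Synthetic model generation, parametrization from oracles, and exact
## quantum-dynamics oracles for small models.

#' Specification of a synthetic excited-state manifold
#'
#' Describes the statistical structure of a synthetic LVC model emulating
#' the photophysics of a rhenium-carbonyl chromophore stacked with a
#' tryptophan donor: low-lying charge-separated (CS, Trp to Dmp) states
#' with small oscillator strengths and weak spin-orbit coupling, higher
#' metal-to-ligand charge-transfer (MLCT) and intraligand (IL) states with
#' large SOC, plus LLCT / AC / AMCS / MC minorities.  The defaults mirror
#' the class counts and energy ranges of the packaged vertical-excitation
#' fixture (19 excited singlets, 17 triplets) and a 192-mode harmonic
#' reference.
#'
#' @param singlet_counts,triplet_counts named integer vectors of excited
#'   state counts per character class.
#' @param energy_ranges named list of c(lo, hi) vertical-energy ranges per
#'   class (eV).
#' @param f_ranges named list of c(lo, hi) oscillator-strength ranges per
#'   class (singlets).
#' @param soc_scales named numeric vector: SOC magnitude scale per class
#'   (eV); a coupling between states of classes a and b is drawn with
#'   scale sqrt(scale_a * scale_b).
#' @param n_modes number of normal modes.
#' @param freq_range c(lo, hi) frequency range (cm^-1), sampled uniformly.
#' @param kappa_scale,lambda_scale standard deviations of the intrastate
#'   gradients and interstate couplings (eV per unit Q).
#' @param ct_dominant c(lo, hi) range of the dominant fragment-pair CT
#'   weight per state.
#' @param drop_s0_soc zero the SOC rows/columns of the ground state
#'   (default TRUE).
#' @param seed integer random seed (recorded in the output metadata).
#' @return object of class \code{manifold_spec}.
#' @export
manifold_spec <- function(
    singlet_counts = c(CS = 5L, MLCT = 7L, LLCT = 2L, IL = 2L,
                       AMCS = 1L, MC = 3L),
    triplet_counts = c(CS = 4L, MLCT = 6L, LLCT = 1L, IL = 4L,
                       AC = 1L, MC = 1L),
    energy_ranges = list(CS = c(2.7, 4.05), MLCT = c(3.15, 4.05),
                         LLCT = c(3.7, 4.0), IL = c(2.95, 4.25),
                         AMCS = c(4.15, 4.25), AC = c(3.4, 3.5),
                         MC = c(3.85, 4.4)),
    f_ranges = list(CS = c(0.001, 0.011), MLCT = c(0.003, 0.107),
                    LLCT = c(0.000, 0.016), IL = c(0.002, 0.003),
                    AMCS = c(0.001, 0.001), AC = c(0.000, 0.001),
                    MC = c(0.001, 0.032)),
    soc_scales = c(CS = 0.001, MLCT = 0.04, LLCT = 0.01, IL = 0.01,
                   AMCS = 0.005, AC = 0.001, MC = 0.04),
    n_modes = 192L,
    freq_range = c(60, 3600),
    kappa_scale = 0.05,
    lambda_scale = 0.01,
    ct_dominant = c(0.90, 0.97),
    drop_s0_soc = TRUE,
    seed = 1L) {
  singlet_counts <- unlist(singlet_counts)  # tolerate JSON-config lists
  triplet_counts <- unlist(triplet_counts)
  energy_ranges <- lapply(energy_ranges, unlist)
  f_ranges <- lapply(f_ranges, unlist)
  soc_scales <- unlist(soc_scales)
  singlet_counts <- singlet_counts[singlet_counts > 0]
  triplet_counts <- triplet_counts[triplet_counts > 0]
  if (sum(singlet_counts) + sum(triplet_counts) < 1L)
    stop("manifold must contain at least one excited state")
  if (any(c(singlet_counts, triplet_counts) < 0))
    stop("state counts must be >= 0")
  for (cls in unique(c(names(singlet_counts), names(triplet_counts)))) {
    er <- energy_ranges[[cls]]
    if (is.null(er) || length(er) != 2L || er[1] > er[2])
      stop("missing or unordered energy range for class ", cls)
  }
  if (n_modes < 1L) stop("need at least one mode")
  if (freq_range[1] <= 0 || freq_range[1] > freq_range[2])
    stop("freq_range must be ordered and positive")
  structure(
    list(singlet_counts = singlet_counts, triplet_counts = triplet_counts,
         energy_ranges = energy_ranges, f_ranges = f_ranges,
         soc_scales = soc_scales, n_modes = as.integer(n_modes),
         freq_range = freq_range, kappa_scale = kappa_scale,
         lambda_scale = lambda_scale, ct_dominant = ct_dominant,
         drop_s0_soc = drop_s0_soc, seed = as.integer(seed)),
    class = "manifold_spec")
}

## class -> dominant hole->electron fragment pair (fragment indices into
## c(Trp, His, Dmp, ReCO3, Rest))
class_dominant_pair <- function(cls) {
  switch(cls,
         CS = c(1L, 3L), MLCT = c(4L, 3L), LLCT = c(2L, 3L),
         IL = c(3L, 3L), AC = c(1L, 1L), AMCS = c(1L, 4L),
         MC = c(4L, 4L),
         stop("unknown character class ", cls))
}

#' Generate a synthetic LVC model
#'
#' Draws a complete, reproducible LVC model (harmonic reference, diabatic
#' parameters, SOC, transition dipoles, CT-number table) from a
#' \code{\link{manifold_spec}}.  CS states receive a dominant Trp-to-Dmp
#' CT weight and SOC drawn from the small CS scale; MLCT states a dominant
#' metal-to-Dmp weight and large SOC.  Oscillator strengths are realised
#' through the S0-to-state transition dipoles,
#' \eqn{|\mu_{0n}|^2 = 3 f_n / (2\Delta E_n)} (atomic units).  The same
#' seed reproduces the identical serialized model.
#'
#' @param spec a \code{manifold_spec}.
#' @return an \code{lvc_model} with CT table; attributes \code{spec} and
#'   \code{classes} record the generation metadata.
#' @export
generate_synthetic_model <- function(spec) {
  stopifnot(inherits(spec, "manifold_spec"))
  set.seed(spec$seed)
  nf <- spec$n_modes

  ## harmonic reference: enough atoms for nf internal modes
  n_atoms <- max(2L, ceiling((nf + 6L) / 3L))
  coords <- matrix(stats::rnorm(3L * n_atoms, sd = 2), n_atoms, 3L)
  masses <- sample(c(1.008, 12.011, 14.007, 15.999, 186.207), n_atoms,
                   replace = TRUE, prob = c(0.3, 0.4, 0.1, 0.18, 0.02))
  omega <- sort(stats::runif(nf, spec$freq_range[1], spec$freq_range[2]))
  K <- qr.Q(qr(matrix(stats::rnorm(3L * n_atoms * nf), 3L * n_atoms, nf)))
  reference <- harmonic_reference(coords, masses, omega, K)

  ## electronic manifold: draw class energies, sort within multiplicity
  draw_block <- function(counts) {
    cls <- rep(names(counts), counts)
    e <- vapply(cls, function(k)
      stats::runif(1, spec$energy_ranges[[k]][1],
                   spec$energy_ranges[[k]][2]), numeric(1))
    ord <- order(e)
    list(classes = cls[ord], energies = e[ord])
  }
  sb <- draw_block(spec$singlet_counts)
  tb <- draw_block(spec$triplet_counts)
  ns <- length(sb$classes) + 1L
  nt <- length(tb$classes)
  basis <- electronic_basis(ns, nt)
  classes <- c("GS", sb$classes, tb$classes)
  epsilon <- c(0, sb$energies, tb$energies)
  n_sf <- basis$n_sf

  ## kappa / lambda: excited states only; couplings within multiplicity
  kappa <- matrix(0, n_sf, nf)
  exc <- seq_len(n_sf)[-1L]
  kappa[exc, ] <- stats::rnorm(length(exc) * nf, sd = spec$kappa_scale)
  lam <- array(0, c(n_sf, n_sf, nf))
  mult <- basis$multiplicity
  for (i in exc) for (j in exc) {
    if (j <= i || mult[i] != mult[j]) next
    v <- stats::rnorm(nf, sd = spec$lambda_scale)
    lam[i, j, ] <- v
    lam[j, i, ] <- v
  }

  ## SOC: singlet-triplet and triplet-triplet blocks, complex Gaussian with
  ## class-pair scale sqrt(s_i s_j); Hermitian by construction
  D <- basis$dim
  map <- spin_expansion_map(basis)
  msv <- spin_expansion_ms(basis)
  soc <- matrix(0 + 0i, D, D)
  scale_of <- function(i) {
    cls <- classes[i]
    if (cls == "GS") spec$soc_scales[["MLCT"]] else spec$soc_scales[[cls]]
  }
  for (a in seq_len(D)) for (b in seq_len(D)) {
    if (b <= a) next
    ia <- map[a]; ib <- map[b]
    if (ia == ib) next
    both_singlet <- mult[ia] == 1L && mult[ib] == 1L
    same_state_pair_same_ms <- mult[ia] == mult[ib] && msv[a] != msv[b]
    if (both_singlet || same_state_pair_same_ms) next
    s <- sqrt(scale_of(ia) * scale_of(ib))
    if (s > 0) {
      v <- complex(real = stats::rnorm(1, sd = s / sqrt(2)),
                   imaginary = stats::rnorm(1, sd = s / sqrt(2)))
      soc[a, b] <- v
      soc[b, a] <- Conj(v)
    }
  }
  if (spec$drop_s0_soc) { soc[1L, ] <- 0 + 0i; soc[, 1L] <- 0 + 0i }

  ## transition dipoles: realise class-wise oscillator strengths
  dip <- replicate(3, matrix(0, n_sf, n_sf), simplify = FALSE)
  for (i in 2L:ns) {
    fr <- spec$f_ranges[[classes[i]]]
    f <- stats::runif(1, fr[1], fr[2])
    mu2 <- 3 * f / (2 * ev2au(epsilon[i]))
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2)) * sqrt(mu2)
    for (cc in 1:3) {
      dip[[cc]][1L, i] <- dir[cc]
      dip[[cc]][i, 1L] <- dir[cc]
    }
  }
  ## small random excited-excited dipoles within the singlet block
  if (ns > 2L) for (i in 2L:(ns - 1L)) for (j in (i + 1L):ns) {
    v <- stats::rnorm(3, sd = 0.1)
    for (cc in 1:3) {
      dip[[cc]][i, j] <- v[cc]
      dip[[cc]][j, i] <- v[cc]
    }
  }
  names(dip) <- c("x", "y", "z")

  ## CT-number table: dominant pair per class plus scattered remainder
  fragments <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
  nfr <- 5L
  om <- array(0, c(n_sf, n_sf, nfr, nfr))
  om[1L, 1L, 5L, 5L] <- 1
  for (i in exc) {
    dom <- class_dominant_pair(classes[i])
    w <- stats::runif(1, spec$ct_dominant[1], spec$ct_dominant[2])
    om[i, i, dom[1], dom[2]] <- w
    rest <- stats::runif(nfr * nfr)
    rest <- rest / sum(rest) * (1 - w)
    om[i, i, , ] <- om[i, i, , ] + matrix(rest, nfr, nfr)
  }
  ## transition CT numbers for same-multiplicity excited pairs
  for (i in exc) for (j in exc) {
    if (j <= i || mult[i] != mult[j]) next
    a <- class_dominant_pair(classes[i]); b <- class_dominant_pair(classes[j])
    v <- stats::runif(1, 0, 0.05)
    om[i, j, a[1], a[2]] <- om[i, j, a[1], a[2]] + v / 2
    om[i, j, b[1], b[2]] <- om[i, j, b[1], b[2]] + v / 2
    om[j, i, , ] <- om[i, j, , ]
  }
  ct <- ct_number_table(fragments, om, basis$labels)

  params <- lvc_parameters(basis, epsilon, kappa, lam, soc, dip)
  model <- lvc_model(reference, params, ct)
  attr(model, "spec") <- spec
  attr(model, "classes") <- classes
  model
}

## ---------------------------------------------------------------------
## Parametrization from oracles

## Project a Cartesian gradient-like vector (eV/Angstrom) onto the mode
## basis (eV per unit Q); exact inverse of modes_to_cartesian on the mode
## subspace.
cartesian_to_modes <- function(reference, grad_cart) {
  g <- as.numeric(t(as.matrix(grad_cart))) / lvc_units$bohr_per_angstrom
  m_au <- rep(reference$masses * lvc_units$me_per_amu, each = 3L)
  w_au <- ev2au(cm12ev(reference$omega))
  as.numeric(crossprod(reference$K, g / sqrt(m_au))) / sqrt(w_au)
}

#' Parametrize intrastate gradients from a gradient oracle
#'
#' Obtains \eqn{\kappa^{(n)}_i} by projecting the oracle's Cartesian
#' excited-state gradients at the reference geometry onto the normal-mode
#' basis and subtracting the ground-state part (state 1).
#'
#' @param gradient_oracle function(state_index) returning the Cartesian
#'   gradient (eV/Angstrom, n_atoms x 3 or length 3*n_atoms) of that
#'   spin-free state at the reference geometry.
#' @param reference a \code{harmonic_reference}.
#' @param n_states number of spin-free states (ground state = 1).
#' @return matrix n_states x F of \eqn{\kappa} values (eV per unit Q),
#'   zero row for the ground state.
#' @export
parametrize_kappa <- function(gradient_oracle, reference, n_states) {
  nf <- reference$n_modes
  kap <- matrix(0, n_states, nf)
  g0 <- tryCatch(cartesian_to_modes(reference, gradient_oracle(1L)),
                 error = function(e)
                   stop("gradient oracle failed for state 1: ",
                        conditionMessage(e)))
  for (nidx in seq_len(n_states)[-1L]) {
    gn <- tryCatch(cartesian_to_modes(reference, gradient_oracle(nidx)),
                   error = function(e)
                     stop(sprintf("gradient oracle failed for state %d: %s",
                                  nidx, conditionMessage(e))))
    kap[nidx, ] <- gn - g0
  }
  kap
}

#' Parametrize interstate couplings from a wavefunction-overlap oracle
#'
#' Finite-difference diabatization: for each mode the oracle supplies the
#' overlap matrices \eqn{S^{\pm} = \langle \phi_n(0) | \phi_m(\pm h e_i)
#' \rangle} between reference adiabatic states and states at geometries
#' displaced by \eqn{\pm h} along the mode.  The antisymmetric part of the
#' two-sided difference estimates the derivative coupling, which scaled by
#' the vertical energy gap yields
#' \eqn{\lambda^{(n,m)}_i = (\epsilon_m - \epsilon_n)\,
#' (S^+ - S^{+T} - S^- + S^{-T})_{nm} / (4h)}.
#'
#' @param overlap_oracle function(Q) returning the n_states x n_states
#'   overlap matrix for mode coordinates Q.
#' @param epsilon vertical energies of the diabatic states (eV).
#' @param multiplicity per-state multiplicities (couplings are restricted
#'   to equal multiplicity).
#' @param n_modes number of modes.
#' @param step displacement h in mass-frequency-weighted coordinates.
#' @param two_sided use the two-sided stencil (default); one-sided uses
#'   the reference overlap (identity) as the second point.
#' @return array n_states x n_states x F of \eqn{\lambda} values
#'   (eV per unit Q), symmetric in the state indices.
#' @export
parametrize_lambda <- function(overlap_oracle, epsilon, multiplicity,
                               n_modes, step = 0.05, two_sided = TRUE) {
  if (step <= 0) stop("step must be positive")
  n <- length(epsilon)
  lam <- array(0, c(n, n, n_modes))
  gap <- outer(epsilon, epsilon, function(a, b) b - a)  # eps_m - eps_n
  same_mult <- outer(multiplicity, multiplicity, "==")
  for (i in seq_len(n_modes)) {
    Q <- numeric(n_modes)
    Q[i] <- step
    Sp <- overlap_oracle(Q)
    Sm <- if (two_sided) overlap_oracle(-Q) else diag(n)
    for (S in list(Sp, Sm)) {
      dev <- max(abs(crossprod(S) - diag(n)))
      if (dev > 0.1)
        warning(sprintf(
          "overlap matrix far from orthogonal (deviation %.3g) at mode %d",
          dev, i))
    }
    h <- if (two_sided) 4 * step else 2 * step
    d <- (Sp - t(Sp) - Sm + t(Sm)) / h
    L <- gap * d * same_mult
    lam[, , i] <- (L + t(L)) / 2
  }
  lam
}

## ---------------------------------------------------------------------
## Exact quantum-dynamics oracles

#' Exact quantum dynamics for small LVC models
#'
#' Numerically exact unitary reference propagation for validating the
#' surface-hopping machinery.  Two regimes are supported: frozen nuclei
#' (matrix exponential of the full spin-expanded Hamiltonian at fixed Q,
#' any model size) and full vibronic wavepacket dynamics in a harmonic
#' oscillator product basis (models restricted to at most 3 spin-free
#' states and 2 modes).  The initial vibrational state is the ground
#' oscillator state |0>, matching the Wigner distribution sampled for the
#' surface-hopping ensemble.
#'
#' @param model an \code{lvc_model}.
#' @param c0 complex initial electronic coefficients, length D
#'   (spin-expanded diabatic basis).
#' @param times numeric vector of output times (fs).
#' @param frozen_Q if non-NULL, propagate with nuclei frozen at these mode
#'   coordinates.
#' @param n_basis harmonic-oscillator basis size per mode (grid regime).
#' @return list with \code{times}, \code{populations} (length(times) x D,
#'   diabatic populations), \code{norm} (conserved to 1e-10) and
#'   \code{singlet}/\code{triplet} totals.
#' @export
exact_quantum_oracle <- function(model, c0, times, frozen_Q = NULL,
                                 n_basis = 40L) {
  p <- model$parameters
  basis <- p$basis
  D <- basis$dim
  c0 <- as.complex(c0)
  if (length(c0) != D) stop("c0 must have length D")
  nrm <- sqrt(sum(Mod(c0)^2))
  if (nrm == 0) stop("c0 must not vanish")
  c0 <- c0 / nrm
  hbar <- lvc_units$hbar_ev_fs
  map <- spin_expansion_map(basis)

  if (!is.null(frozen_Q)) {
    pot <- evaluate_potential(model, frozen_Q, derivatives = FALSE)
    H <- spin_expand_matrix(basis, pot$V) + p$soc
    eg <- eigen((H + Conj(t(H))) / 2)
    a0 <- Conj(t(eg$vectors)) %*% c0
    pops <- t(vapply(times, function(tt) {
      ct <- eg$vectors %*% (exp(-1i * eg$values * tt / hbar) * a0)
      Mod(ct)^2
    }, numeric(D)))
  } else {
    nf <- model$reference$n_modes
    if (basis$n_sf > 3L || nf > 2L)
      stop("vibronic oracle limited to <= 3 spin-free states and <= 2 ",
           "modes; use frozen_Q for larger models")
    N <- as.integer(n_basis)
    dim_tot <- D * N^nf
    if (dim_tot > 4000L)
      stop(sprintf("vibronic basis too large (%d > 4000); reduce n_basis",
                   dim_tot))
    hw <- mode_quantum_ev(model$reference)
    ## per-mode operators in the HO basis
    Qop <- function() {
      M <- matrix(0, N, N)
      for (v in seq_len(N - 1L))
        M[v, v + 1L] <- M[v + 1L, v] <- sqrt(v / 2)
      M
    }
    Nop <- diag(seq_len(N) - 1L)
    I_N <- diag(N)
    kron_mode <- function(op_list) Reduce(kronecker, op_list)
    vib_ident <- kron_mode(replicate(nf, I_N, simplify = FALSE))
    vib_Q <- lapply(seq_len(nf), function(i) {
      ops <- replicate(nf, I_N, simplify = FALSE)
      ops[[i]] <- Qop()
      kron_mode(ops)
    })
    vib_H0 <- Reduce(`+`, lapply(seq_len(nf), function(i) {
      ops <- replicate(nf, I_N, simplify = FALSE)
      ops[[i]] <- hw[i] * (Nop + 0.5 * I_N)
      kron_mode(ops)
    }))
    nv <- N^nf
    H <- matrix(0 + 0i, dim_tot, dim_tot)
    blk <- function(a) ((a - 1L) * nv + 1L):(a * nv)
    for (a in seq_len(D)) {
      sa <- map[a]
      Ha <- vib_H0 + p$epsilon[sa] * vib_ident
      for (i in seq_len(nf))
        Ha <- Ha + p$kappa[sa, i] * vib_Q[[i]]
      H[blk(a), blk(a)] <- H[blk(a), blk(a)] + Ha
      for (b in seq_len(D)) {
        if (b == a) next
        sb <- map[b]
        W <- matrix(0, nv, nv)
        coupled <- spin_expansion_ms(basis)[a] == spin_expansion_ms(basis)[b] &&
          basis$multiplicity[sa] == basis$multiplicity[sb]
        if (coupled && sa != sb) {
          for (i in seq_len(nf))
            if (p$lam[sa, sb, i] != 0)
              W <- W + p$lam[sa, sb, i] * vib_Q[[i]]
        }
        H[blk(a), blk(b)] <- H[blk(a), blk(b)] + W + p$soc[a, b] * vib_ident
      }
    }
    eg <- eigen((H + Conj(t(H))) / 2)
    psi0 <- complex(length.out = dim_tot)
    for (a in seq_len(D)) psi0[(a - 1L) * nv + 1L] <- c0[a]  # |v=0> per mode
    a0 <- Conj(t(eg$vectors)) %*% psi0
    pops <- t(vapply(times, function(tt) {
      psi <- eg$vectors %*% (exp(-1i * eg$values * tt / hbar) * a0)
      vapply(seq_len(D), function(a) sum(Mod(psi[blk(a)])^2), numeric(1))
    }, numeric(D)))
  }
  norm <- rowSums(pops)
  mult_exp <- basis$multiplicity[map]
  list(times = times, populations = pops, norm = norm,
       singlet = rowSums(pops[, mult_exp == 1L, drop = FALSE]),
       triplet = rowSums(pops[, mult_exp == 3L, drop = FALSE]))
}
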