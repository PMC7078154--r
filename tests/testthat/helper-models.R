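## Shared toy-model builders.  All fixtures are built in code; seeds are
## fixed so every test is deterministic.

## random orthonormal mode matrix for n_atoms atoms / F modes
toy_K <- function(n_atoms, nf, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(3 * n_atoms * nf), 3 * n_atoms, nf)))
}

toy_reference <- function(omega = c(500, 1000, 1500), n_atoms = 2,
                          seed = 1, coords = NULL,
                          masses = NULL) {
  set.seed(seed)
  if (is.null(coords)) coords <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
  if (is.null(masses)) masses <- rep(12, n_atoms)
  harmonic_reference(coords, masses, omega,
                     toy_K(n_atoms, length(omega), seed))
}

## 2 singlets + 1 triplet, 3 modes, with kappa, lambda and complex SOC
toy_model_2s1t <- function(lam12 = c(0.05, 0, 0),
                           soc_v = 0.01 + 0.002i,
                           epsilon = c(0, 2.5, 2.4)) {
  ref <- toy_reference()
  basis <- electronic_basis(2, 1)
  lam <- array(0, c(3, 3, 3))
  lam[1, 2, ] <- lam[2, 1, ] <- lam12
  soc <- matrix(0 + 0i, 5, 5)
  soc[2, 3] <- soc_v
  soc[3, 2] <- Conj(soc_v)
  kappa <- matrix(c(0, 0, 0, 0.1, 0, 0, -0.05, 0, 0), 3, 3, byrow = TRUE)
  lvc_model(ref, lvc_parameters(basis, epsilon, kappa, lam, soc))
}

## frozen-nuclei two-level model: 1 singlet + 1 triplet, SOC between the
## singlet and the MS = 0 triplet component
rabi_model <- function(v = 0.02, Delta = 0.05) {
  ref <- toy_reference(omega = 400, n_atoms = 2, seed = 5,
                       coords = matrix(0, 2, 3))
  basis <- electronic_basis(1, 1)
  soc <- matrix(0 + 0i, 4, 4)
  soc[1, 3] <- v
  soc[3, 1] <- Conj(v)
  lvc_model(ref, lvc_parameters(basis, c(0, Delta), n_modes = 1,
                                soc = soc))
}

## singlet/triplet crossing toy for the surface-hopping vs exact-quantum
## comparison: one photoexcited singlet, two triplet acceptor states, two
## incommensurate modes; crossing seam displaced from the Franck-Condon
## region; weak constant SOC to all six triplet components.
crossing_toy_model <- function() {
  ref <- toy_reference(omega = c(400, 620), n_atoms = 4, seed = 1,
                       coords = matrix(0, 4, 3))
  basis <- electronic_basis(1, 2)
  lam <- array(0, c(3, 3, 2))
  v <- 0.004
  soc <- matrix(0 + 0i, 7, 7)
  soc[1, 2:7] <- v
  soc[2:7, 1] <- v
  kappa <- matrix(c(-0.06, -0.05,
                    -0.02, -0.035,
                    -0.035, -0.01), 3, 2, byrow = TRUE)
  lvc_model(ref, lvc_parameters(basis, c(0.30, 0.26, 0.22), kappa, lam,
                                soc, n_modes = 2))
}

## a small random model exercising every block (for IO fuzzing etc.)
random_model <- function(seed, ns = 3, nt = 2, nf = 4, with_ct = TRUE) {
  set.seed(seed)
  n_atoms <- max(2, ceiling((nf + 6) / 3))
  ref <- harmonic_reference(matrix(rnorm(3 * n_atoms), n_atoms, 3),
                            runif(n_atoms, 1, 20),
                            sort(runif(nf, 300, 3000)),
                            toy_K(n_atoms, nf, seed + 1))
  basis <- electronic_basis(ns, nt)
  n_sf <- ns + nt
  epsilon <- c(0, sort(runif(n_sf - 1, 1, 5)))
  kappa <- matrix(rnorm(n_sf * nf, sd = 0.05), n_sf, nf)
  kappa[1, ] <- 0
  lam <- array(0, c(n_sf, n_sf, nf))
  mult <- basis$multiplicity
  for (i in 2:n_sf) for (j in 2:n_sf) {
    if (j <= i || mult[i] != mult[j]) next
    v <- rnorm(nf, sd = 0.02)
    lam[i, j, ] <- v
    lam[j, i, ] <- v
  }
  D <- basis$dim
  soc <- matrix(complex(real = rnorm(D * D, sd = 0.01),
                        imaginary = rnorm(D * D, sd = 0.01)), D, D)
  soc <- (soc + Conj(t(soc))) / 2
  ## keep only singlet-triplet and triplet-triplet blocks
  map <- lvcdyn:::spin_expansion_map(basis)
  for (a in seq_len(D)) for (b in seq_len(D)) {
    if (mult[map[a]] == 1 && mult[map[b]] == 1) soc[a, b] <- 0
    if (a == b) soc[a, b] <- 0
  }
  dip <- lapply(1:3, function(cc) {
    m <- matrix(rnorm(n_sf * n_sf, sd = 0.3), n_sf, n_sf)
    m[mult == 1, mult == 3] <- 0
    m[mult == 3, mult == 1] <- 0
    (m + t(m)) / 2
  })
  ct <- NULL
  if (with_ct) {
    frg <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
    om <- array(0, c(n_sf, n_sf, 5, 5))
    om[1, 1, 5, 5] <- 1
    for (n in 2:n_sf) {
      w <- runif(25)
      om[n, n, , ] <- matrix(w / sum(w), 5, 5)
    }
    for (n in 2:n_sf) for (m2 in 2:n_sf) {
      if (m2 <= n || mult[n] != mult[m2]) next
      w <- matrix(runif(25, 0, 0.02), 5, 5)
      om[n, m2, , ] <- w
      om[m2, n, , ] <- w
    }
    ct <- ct_number_table(frg, om, basis$labels)
  }
  lvc_model(ref, lvc_parameters(basis, epsilon, kappa, lam, soc, dip), ct)
}

## diabatic populations of a trajectory's coefficients at every recorded
## step (columns: spin-expanded states)
traj_diabatic_pops <- function(traj, basis) {
  t(vapply(seq_along(traj$times), function(k) {
    A <- lvcdyn:::spin_expand_transform(basis, traj$U_sf[, , k]) %*%
      traj$U_diag[, , k]
    Mod(A %*% traj$c_diag[k, ])^2
  }, numeric(basis$dim)))
}
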