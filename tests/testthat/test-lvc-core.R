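test_that("potential evaluation: Q = 0, one-mode closed form, fixture energies", {
  model <- toy_model_2s1t()
  pot0 <- evaluate_potential(model, c(0, 0, 0))
  expect_equal(pot0$V0, 0)
  expect_equal(diag(pot0$V), c(0, 2.5, 2.4))
  expect_equal(pot0$V[1, 2], 0)

  ## 1 mode, 2 states: eps = (0, 1), lambda = 0.1, Q = 2
  ref1 <- toy_reference(omega = 1000, n_atoms = 2, seed = 2)
  b2 <- electronic_basis(2, 0)
  lam <- array(0, c(2, 2, 1))
  lam[1, 2, 1] <- lam[2, 1, 1] <- 0.1
  m1 <- lvc_model(ref1, lvc_parameters(b2, c(0, 1), lam = lam, n_modes = 1))
  pot <- evaluate_potential(m1, 2)
  expect_equal(pot$V[1, 2], 0.2)
  hw <- 1000 * lvc_units$ev_per_cm1
  expect_equal(pot$V0, hw * 4 / 2)

  ## vertical shifts from the packaged fixture: lowest excited singlet
  fx <- load_table1_fixture()
  expect_equal(fx$parameters$epsilon[2], 2.71)
  ## at Q=0 the lowest excited-singlet eigenvalue is epsilon(S1)
  ref0 <- toy_reference(omega = 500, n_atoms = 13, seed = 4)
  mfx <- lvc_model(ref0, lvc_parameters(fx$basis, fx$parameters$epsilon,
                                        n_modes = 1))
  ad <- adiabatize(evaluate_potential(mfx, 0), fx$basis)
  sing <- ad$E_mch[fx$basis$multiplicity == 1L]
  expect_equal(sort(sing)[2], 2.71)
})

test_that("adiabatize: identity, two-level mixing, residual of random block", {
  b2 <- electronic_basis(2, 0)
  ## diagonal V -> identity transform
  ad <- adiabatize(list(V = diag(c(0.3, 1.1))), b2)
  expect_equal(ad$U, diag(2))
  expect_equal(ad$E_mch, c(0.3, 1.1))

  ## symmetric two-level [[0, c], [c, 0]]: energies -+c, 45 degree mixing
  cc <- 0.37
  ad2 <- adiabatize(list(V = matrix(c(0, cc, cc, 0), 2, 2)), b2)
  expect_equal(ad2$E_mch, c(-cc, cc))
  expect_equal(abs(ad2$U), matrix(rep(1 / sqrt(2), 4), 2, 2),
               tolerance = 1e-12)

  ## random 5-state block: eigenvalues vs characteristic polynomial roots,
  ## eigenvectors verified by their residuals (independent of eigen())
  set.seed(9)
  b5 <- electronic_basis(5, 0)
  V <- matrix(rnorm(25), 5, 5)
  V <- (V + t(V)) / 2
  ad5 <- adiabatize(list(V = V), b5)
  cf <- sapply(0:5, function(k) {
    ## coefficients of det(V - x I) via elementary symmetric polynomials
    if (k == 0) return(1)
    combs <- utils::combn(5, k)
    (-1)^k * sum(apply(combs, 2, function(idx)
      det(V[idx, idx, drop = FALSE])))
  })
  ## polynomial x^5 + cf[2] x^4 + ... (char poly of V, monic)
  roots <- sort(Re(polyroot(rev(cf))))
  expect_equal(ad5$E_mch, roots, tolerance = 1e-10)
  for (k in 1:5)
    expect_lt(max(abs(V %*% ad5$U[, k] - ad5$E_mch[k] * ad5$U[, k])), 1e-10)
})

test_that("MCH gradients and NACs: lambda-free closed form, FD, antisymmetry", {
  ## lambda = 0: gradient of state n along mode i is hbar w_i Q_i + kappa,
  ## NAC vanishes
  model0 <- toy_model_2s1t(lam12 = c(0, 0, 0))
  Q <- c(0.4, -0.3, 0.2)
  pot <- evaluate_potential(model0, Q)
  ad <- adiabatize(pot, model0$parameters$basis)
  hw <- lvcdyn:::mode_quantum_ev(model0$reference)
  g2 <- mch_gradient_and_nac(ad, pot, model0, 2, 1)
  expect_equal(g2$grad_modes, hw * Q + model0$parameters$kappa[2, ],
               tolerance = 1e-12)
  expect_equal(g2$nac_modes, rep(0, 3))

  ## random coupled model: analytic vs central differences
  model <- random_model(21, ns = 3, nt = 1, nf = 4, with_ct = FALSE)
  basis <- model$parameters$basis
  set.seed(22)
  Q <- rnorm(4, sd = 0.5)
  pot <- evaluate_potential(model, Q)
  ad <- adiabatize(pot, basis)
  h <- 1e-5
  for (n in c(1, 2, 4)) {
    g <- mch_gradient_and_nac(ad, pot, model, n)$grad_modes
    fd <- vapply(1:4, function(i) {
      ev <- function(s) {
        qq <- Q
        qq[i] <- qq[i] + s * h
        adiabatize(evaluate_potential(model, qq), basis)$E_mch[n]
      }
      (ev(1) - ev(-1)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-6)
  }

  ## NAC antisymmetry
  n12 <- mch_gradient_and_nac(ad, pot, model, 1, 2)$nac_modes
  n21 <- mch_gradient_and_nac(ad, pot, model, 2, 1)$nac_modes
  expect_equal(n12, -n21, tolerance = 1e-12)
  expect_error(mch_gradient_and_nac(ad, pot, model, 2, 2), "distinct")

  ## exact degeneracy: NAC flagged unreliable, magnitude capped at the floor
  b2d <- electronic_basis(2, 0)
  lam0 <- array(0, c(2, 2, 1))
  ref1 <- toy_reference(omega = 500, n_atoms = 2, seed = 23)
  mdeg <- lvc_model(ref1, lvc_parameters(
    b2d, c(1, 1), kappa = matrix(c(0.1, 0.2), 2, 1), lam = lam0,
    n_modes = 1))
  pd <- evaluate_potential(mdeg, 0)
  add <- adiabatize(pd, b2d)
  nac <- mch_gradient_and_nac(add, pd, mdeg, 1, 2, floor_ev = 1e-8)
  expect_false(nac$reliable)
  expect_true(all(is.finite(nac$nac_modes)))
})

test_that("property transforms: identity, unitary invariance, trace", {
  model <- random_model(31, ns = 3, nt = 2, nf = 3, with_ct = FALSE)
  p <- model$parameters
  basis <- p$basis
  n_sf <- basis$n_sf

  tp <- transform_properties(diag(n_sf), basis, soc = p$soc,
                             dipoles = p$dipoles)
  expect_equal(tp$soc_mch, p$soc)
  expect_equal(tp$dipoles_mch$x, p$dipoles$x)

  ## spectrum of the SOC-including Hamiltonian is invariant under an extra
  ## random block-orthogonal transform of the diabatic basis
  set.seed(32)
  Q <- rnorm(3, sd = 0.3)
  pot <- evaluate_potential(model, Q)
  ad <- adiabatize(pot, basis)
  soc_mch <- transform_properties(ad$U, basis, soc = p$soc)$soc_mch
  dg <- build_diagonal(ad$E_mch, soc_mch, basis)

  ## rotate the diabatic basis (within multiplicity blocks) and repeat
  R <- matrix(0, n_sf, n_sf)
  for (m in c(1, 3)) {
    idx <- which(basis$multiplicity == m)
    R[idx, idx] <- qr.Q(qr(matrix(rnorm(length(idx)^2), length(idx))))
  }
  V2 <- t(R) %*% pot$V %*% R
  Rx <- lvcdyn:::spin_expand_transform(basis, R)
  soc2 <- Conj(t(Rx)) %*% p$soc %*% Rx
  ad2 <- adiabatize(list(V = V2), basis)
  soc_mch2 <- transform_properties(ad2$U, basis, soc = soc2)$soc_mch
  dg2 <- build_diagonal(ad2$E_mch, soc_mch2, basis)
  expect_equal(dg$E_diag, dg2$E_diag, tolerance = 1e-10)

  ## similarity invariant: dipole traces conserved
  tpU <- transform_properties(ad$U, basis, dipoles = p$dipoles)
  for (cc in c("x", "y", "z"))
    expect_equal(sum(diag(tpU$dipoles_mch[[cc]])),
                 sum(diag(p$dipoles[[cc]])), tolerance = 1e-12)
  expect_error(transform_properties(ad$U, basis,
                                    soc = p$soc + 0.1i * diag(basis$dim)),
               "Hermitian")
})

test_that("diagonal representation: SOC = 0 limit, two-level gap, norms", {
  model <- random_model(41, ns = 2, nt = 2, nf = 3, with_ct = FALSE)
  basis <- model$parameters$basis
  pot <- evaluate_potential(model, c(0.1, -0.2, 0.3))
  ad <- adiabatize(pot, basis)
  D <- basis$dim
  map <- lvcdyn:::spin_expansion_map(basis)

  dg0 <- build_diagonal(ad$E_mch, matrix(0 + 0i, D, D), basis)
  expect_equal(dg0$E_diag, sort(ad$E_mch[map]))

  ## 1 singlet + 1 triplet with constant coupling v to MS=0: avoided
  ## crossing at degeneracy opens a gap of exactly 2|v|
  v <- 0.013 + 0.007i
  b11 <- electronic_basis(1, 1)
  soc <- matrix(0 + 0i, 4, 4)
  soc[1, 3] <- v
  soc[3, 1] <- Conj(v)
  dg <- build_diagonal(c(1, 1), soc, b11)
  gapped <- range(dg$E_diag)
  expect_equal(diff(gapped), 2 * Mod(v), tolerance = 1e-12)
  expect_equal(apply(Mod(dg$U_diag)^2, 2, sum), rep(1, 4),
               tolerance = 1e-12)
})

test_that("time overlaps: identity, sign flips, unitarity", {
  set.seed(51)
  D <- 6
  A <- matrix(complex(real = rnorm(D * D), imaginary = rnorm(D * D)), D, D)
  U <- eigen((A + Conj(t(A))) / 2)$vectors  # unitary
  expect_equal(time_overlap(U, U), diag(D) + 0i, tolerance = 1e-12)

  U2 <- U
  U2[, 3] <- -U2[, 3]
  expect_equal(time_overlap(U, U2), diag(D) + 0i, tolerance = 1e-12)

  B <- matrix(complex(real = rnorm(D * D), imaginary = rnorm(D * D)), D, D)
  U3 <- eigen((B + Conj(t(B))) / 2)$vectors
  S <- time_overlap(U, U3)
  expect_lt(max(abs(Conj(t(S)) %*% S - diag(D))), 1e-10)
})

test_that("truncation: mode cutoff, state removal, identity", {
  ## 192 modes with the lowest 34 below the 300 cm^-1 cutoff -> 158 left
  n_atoms <- 66
  omega <- c(seq(50, 295, length.out = 34), seq(305, 3600, length.out = 158))
  ref <- harmonic_reference(matrix(rnorm(3 * n_atoms), n_atoms, 3),
                            rep(12, n_atoms), omega,
                            toy_K(n_atoms, 192, seed = 61))
  basis <- electronic_basis(30, 30)
  par <- lvc_parameters(basis, c(0, seq_len(59) / 10), n_modes = 192)
  model <- lvc_model(ref, par)

  tr1 <- truncate_model(model, omega_cut = 300)
  expect_equal(tr1$reference$n_modes, 158L)

  ## removing S20..S29 and T16, T18, T20..T30 leaves 20 singlets + 17 triplets
  drop <- c(paste0("S", 20:29), "T16", "T18", paste0("T", 20:30))
  tr2 <- truncate_model(model, remove_states = drop)
  expect_equal(tr2$parameters$basis$n_singlets, 20L)
  expect_equal(tr2$parameters$basis$n_triplets, 17L)
  expect_silent(validate_lvc_parameters(tr2$parameters))

  ## identity truncation reserializes byte-for-byte
  small <- random_model(62, ns = 3, nt = 2, nf = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_lvc_model(small, f1)
  write_lvc_model(truncate_model(small, 0, NULL, FALSE), f2)
  expect_identical(readLines(f1), readLines(f2))

  ## S0-SOC zeroing and error paths
  trs <- truncate_model(small, drop_s0_soc = TRUE)
  expect_true(all(trs$parameters$soc[1, ] == 0))
  expect_true(all(trs$parameters$soc[, 1] == 0))
  expect_error(truncate_model(small, omega_cut = 1e6), "every mode")
  expect_error(truncate_model(small, remove_states = "S0"), "ground state")
})

test_that("degenerate-state relabeling leaves the spectrum invariant", {
  ## permuting degenerate diabatic states (consistently in eps, kappa,
  ## lambda) must not change the eigenvalues at any Q
  ref <- toy_reference(omega = c(600, 900), n_atoms = 2, seed = 71)
  b <- electronic_basis(3, 0)
  eps <- c(0, 2.0, 2.0)
  kap <- matrix(c(0, 0, 0.05, 0.02, 0.05, 0.02), 3, 2, byrow = TRUE)
  lam <- array(0, c(3, 3, 2))
  lam[1, 2, ] <- lam[2, 1, ] <- c(0.03, 0.01)
  lam[1, 3, ] <- lam[3, 1, ] <- c(0.02, -0.01)
  m <- lvc_model(ref, lvc_parameters(b, eps, kap, lam, n_modes = 2))
  perm <- c(1, 3, 2)
  m2 <- lvc_model(ref, lvc_parameters(
    b, eps[perm], kap[perm, ], lam[perm, perm, ], n_modes = 2))
  set.seed(72)
  for (rep in 1:5) {
    Q <- rnorm(2)
    e1 <- adiabatize(evaluate_potential(m, Q), b)$E_mch
    e2 <- adiabatize(evaluate_potential(m2, Q), b)$E_mch
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})
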