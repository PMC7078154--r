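## build a minimal hand-made "archive" with known content for estimator
## oracles: D = 2 (2 singlets), identity or chosen transforms
hand_trajectory <- function(c_list, active, U_diag_list = NULL,
                            basis = electronic_basis(2, 0)) {
  n <- length(active)
  D <- basis$dim
  if (is.null(U_diag_list))
    U_diag_list <- replicate(n, diag(D) + 0i, simplify = FALSE)
  structure(list(
    times = seq(0, by = 0.5, length.out = n),
    Q = matrix(0, n, 1), P = matrix(0, n, 1),
    active = active,
    E_mch = matrix(0, n, basis$n_sf), E_diag = matrix(0, n, D),
    c_diag = do.call(rbind, c_list),
    U_sf = array(diag(basis$n_sf), c(basis$n_sf, basis$n_sf, n)),
    U_diag = array(unlist(U_diag_list), c(D, D, n)),
    ekin = numeric(n), etot = numeric(n),
    hops = data.frame(), energy_drift = 0, valid = TRUE,
    basis = basis, n_modes = 1, settings = NULL),
    class = "lvc_trajectory")
}

hand_ensemble <- function(trajs, basis = electronic_basis(2, 0)) {
  structure(list(trajectories = trajs, failures = NULL,
                 selections = NULL, settings = list(t_final = 1),
                 basis = basis, n_modes = 1, seed = 1),
            class = "lvc_ensemble")
}

test_that("population estimators against a hand-built archive", {
  ## single trajectory, pure state, identity transforms
  tr <- hand_trajectory(list(c(1 + 0i, 0), c(1 + 0i, 0)), c(1L, 1L))
  ens <- hand_ensemble(list(tr))
  for (est in c("mixed", "active", "coefficient")) {
    pp <- populations(ens, "mch", est)
    expect_equal(pp$S0, c(1, 1))
    expect_equal(pp$S1, c(0, 0))
  }

  ## mixed estimator: coefficients (sqrt(0.8), sqrt(0.2)) but active = 2,
  ## with a 45-degree U_diag; spreadsheet-style direct computation
  th <- pi / 4
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) + 0i
  cvec <- c(sqrt(0.8) + 0i, sqrt(0.2) + 0i)
  tr2 <- hand_trajectory(list(cvec), 2L, list(U))
  ens2 <- hand_ensemble(list(tr2))
  ## by hand: rho = c c^H with diagonal replaced by (0, 1)
  rho <- cvec %*% Conj(t(cvec))
  diag(rho) <- c(0, 1)
  expected <- Re(diag(U %*% rho %*% Conj(t(U))))
  pp2 <- populations(ens2, "mch", "mixed")
  expect_equal(as.numeric(pp2[1, -1]), expected, tolerance = 1e-12)
  ## active estimator: |U[, 2]|^2
  pa <- populations(ens2, "mch", "active")
  expect_equal(as.numeric(pa[1, -1]), Mod(U[, 2])^2, tolerance = 1e-12)
  ## coefficient estimator: |U c|^2
  pc <- populations(ens2, "mch", "coefficient")
  expect_equal(as.numeric(pc[1, -1]), as.numeric(Mod(U %*% cvec)^2),
               tolerance = 1e-12)
  ## every estimator sums to one
  for (est in c("mixed", "active", "coefficient"))
    expect_equal(rowSums(populations(ens2, "mch", est)[, -1]), 1,
                 tolerance = 1e-12)
})

test_that("diabatic populations are invariant under diagonal-state reordering", {
  th <- 0.6
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) + 0i
  cvec <- c(0.6 + 0.3i, sqrt(1 - 0.45) + 0i)
  perm <- matrix(c(0, 1, 1, 0), 2, 2)
  ## swap diagonal states: U columns and coefficient entries permuted
  trA <- hand_trajectory(list(cvec), 1L, list(U))
  trB <- hand_trajectory(list(cvec[c(2, 1)]), 2L, list(U %*% perm))
  pA <- populations(hand_ensemble(list(trA)), "diabatic", "mixed")
  pB <- populations(hand_ensemble(list(trB)), "diabatic", "mixed")
  expect_equal(pA, pB, tolerance = 1e-12)
})

test_that("CT evolution: pure states, cross terms, conservation", {
  basis <- electronic_basis(2, 0)
  frg <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
  om <- array(0, c(2, 2, 5, 5))
  om[1, 1, 5, 5] <- 1                       # ground: rest placeholder
  om[2, 2, 1, 3] <- 0.9; om[2, 2, 3, 3] <- 0.1
  om[1, 2, 2, 3] <- om[2, 1, 2, 3] <- 0.05  # transition CT number
  ct <- ct_number_table(frg, om, c("S0", "S1"))

  ## wavefunction on pure diabatic state 2 -> its diagonal row
  w <- wavefunction_ct_numbers(c(0, 1), ct, basis)
  expect_equal(w["Trp", "Dmp"], 0.9)
  expect_equal(w["Dmp", "Dmp"], 0.1)

  ## equal superposition: hand evaluation with the cross term
  cs <- c(1, 1) / sqrt(2)
  w2 <- wavefunction_ct_numbers(cs, ct, basis)
  ## 0.5*omega11 + 0.5*omega22 + 2*0.5*omega12
  expect_equal(w2["His", "Dmp"], 2 * 0.5 * 0.05, tolerance = 1e-12)
  expect_equal(w2["Trp", "Dmp"], 0.45, tolerance = 1e-12)
  expect_equal(w2["Rest", "Rest"], 0.5, tolerance = 1e-12)

  ## complex coefficients: cross term weighted by 2 Re(c1* c2)
  cc <- c(sqrt(0.5) + 0i, sqrt(0.5) * 1i)
  w3 <- wavefunction_ct_numbers(cc, ct, basis)
  expect_equal(w3["His", "Dmp"], 0, tolerance = 1e-12)

  ## ensemble CT evolution equals the per-trajectory hand calculation and
  ## total CT weight is conserved under the stated normalization
  tr <- hand_trajectory(list(c(1 + 0i, 0) / 1, cs + 0i), c(1L, 1L))
  ens <- hand_ensemble(list(tr))
  ev <- ct_evolution(ens, ct)
  expect_equal(ev$omega_Trp_Dmp, c(0, 0.45), tolerance = 1e-12)
  expect_equal(ev$class_CS, c(0, 0.45), tolerance = 1e-12)
  tot <- rowSums(ev[, startsWith(colnames(ev), "omega_")])
  ## coefficient-weighted diagonal totals: state1 tot = 1, state2 tot = 1
  expect_equal(tot, c(1, 0.5 * 1 + 0.5 * 1 + 2 * 0.5 * 0.05),
               tolerance = 1e-12)
})

test_that("ensemble split by final CS character", {
  basis <- electronic_basis(2, 0)
  frg <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
  om <- array(0, c(2, 2, 5, 5))
  om[1, 1, 4, 3] <- 1           # state 1: pure MLCT
  om[2, 2, 1, 3] <- 1           # state 2: pure CS
  ct <- ct_number_table(frg, om, c("a", "b"))
  tr_mlct <- hand_trajectory(list(c(1 + 0i, 0), c(1 + 0i, 0)), c(1L, 1L))
  tr_cs <- hand_trajectory(list(c(1 + 0i, 0), c(0, 1 + 0i)), c(1L, 2L))
  ens <- hand_ensemble(list(tr_mlct, tr_cs))
  sp <- split_by_cs_character(ens, ct, threshold = 0.5, frame = "final")
  expect_equal(sp$cs, 2L)
  expect_equal(sp$other, 1L)
  expect_equal(sp$fraction, c(0, 1), tolerance = 1e-12)
  sp0 <- split_by_cs_character(ens, ct, frame = "initial")
  expect_equal(length(sp0$cs), 0L)
})

test_that("kinetic model: identities, limits, forward-simulation recovery", {
  ## algebraic identities round-trip to 1e-10
  for (p in list(c(0.6, 10, 97), c(0.2, 5, 300), c(0.95, 30, 400))) {
    der <- lvcdyn:::kinetic_identities(p[1], p[2], p[3])
    back <- lvcdyn:::kinetic_identities_inverse(der$tau1, der$tau2,
                                                der$tauc)
    expect_equal(c(back$R_fast, back$tau_fast, back$tau_slow), p,
                 tolerance = 1e-10)
  }

  ## tau_c -> infinity: no cooling, pure monoexponential hot decay with
  ## tau_fast = tau1 and unit fast fraction
  der <- lvcdyn:::kinetic_identities_inverse(12, 200, Inf)
  expect_equal(der$tau_fast, 12)
  expect_equal(der$R_fast, 1, tolerance = 1e-12)

  ## forward simulation: continuous-time three-species kinetics per
  ## trajectory, then refit; truth within the bootstrap CI
  R_true <- 0.6; tf_true <- 10; ts_true <- 97
  k <- lvcdyn:::kinetic_identities(R_true, tf_true, ts_true)
  set.seed(77)
  n_traj <- 200
  times <- seq(0, 1000, by = 2)
  sim_traj <- function() {
    ## hot: competing ISC (tau1) and cooling (tauc); cold: ISC (tau2)
    t_isc_hot <- rexp(1, 1 / k$tau1)
    t_cool <- if (is.finite(k$tauc)) rexp(1, 1 / k$tauc) else Inf
    t_s <- if (t_isc_hot < t_cool) t_isc_hot else
      t_cool + rexp(1, 1 / k$tau2)
    as.numeric(times < t_s)
  }
  tm <- vapply(seq_len(n_traj), function(i) sim_traj(),
               numeric(length(times)))
  fit <- fit_kinetics(times, rowMeans(tm), traj_matrix = tm,
                      n_boot = 80, seed = 5)
  expect_false(fit$flagged)
  expect_lt(abs(fit$R_fast - R_true), max(2 * fit$ci["R_fast"], 0.05))
  expect_lt(abs(fit$tau_fast - tf_true), max(2 * fit$ci["tau_fast"], 2))
  expect_lt(abs(fit$tau_slow - ts_true), max(2 * fit$ci["tau_slow"], 10))
})

test_that("kinetic-fit recovery across a parameter grid", {
  set.seed(99)
  times <- seq(0, 1000, by = 2)
  for (p in list(c(0.4, 15, 150), c(0.75, 8, 80))) {
    S <- lvcdyn:::biexp_model(times, p[1], p[2], p[3]) +
      rnorm(length(times), sd = 0.004)
    fit <- fit_kinetics(times, S, n_boot = 0)
    expect_lt(abs(fit$R_fast - p[1]), 0.05)
    expect_lt(abs(fit$tau_fast - p[2]) / p[2], 0.15)
    expect_lt(abs(fit$tau_slow - p[3]) / p[3], 0.10)
  }
})

test_that("character classification: mapping and precedence", {
  frg <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
  row <- function(...) {
    m <- matrix(0, 5, 5, dimnames = list(frg, frg))
    for (kv in list(...)) m[kv[[1]], kv[[2]]] <- kv[[3]]
    m
  }
  expect_equal(classify_character(row(list("Trp", "Dmp", 0.96))), "CS")
  expect_equal(classify_character(row(list("ReCO3", "Dmp", 0.7),
                                      list("Dmp", "Dmp", 0.2))), "MLCT")
  expect_equal(classify_character(row(list("His", "Dmp", 0.8))), "LLCT")
  expect_equal(classify_character(row(list("Trp", "Trp", 0.9))), "AC")
  expect_equal(classify_character(row(list("Trp", "ReCO3", 0.6))), "AMCS")
  expect_equal(classify_character(row(list("ReCO3", "ReCO3", 0.6))), "MC")
  expect_equal(classify_character(row(list("Rest", "Rest", 0.9),
                                      list("Trp", "Dmp", 0.05))), "Others")
  expect_equal(classify_character(matrix(0, 5, 5,
                                         dimnames = list(frg, frg))),
               "Others")
  ## exact tie resolved by precedence (CS before MLCT)
  expect_equal(classify_character(row(list("Trp", "Dmp", 0.5),
                                      list("ReCO3", "Dmp", 0.5))), "CS")
})

test_that("coherence descriptors: coherent, random-phase and null ensembles", {
  basis <- electronic_basis(1, 0)
  mk_traj <- function(qtrace) {
    n <- length(qtrace)
    structure(list(times = seq(0, by = 0.5, length.out = n),
                   Q = matrix(qtrace, n, 1), P = matrix(0, n, 1),
                   active = rep(1L, n), E_mch = matrix(0, n, 1),
                   E_diag = matrix(0, n, 1),
                   c_diag = matrix(1 + 0i, n, 1),
                   U_sf = array(1, c(1, 1, n)),
                   U_diag = array(1 + 0i, c(1, 1, n)),
                   ekin = numeric(n), etot = numeric(n),
                   hops = data.frame(), energy_drift = 0, valid = TRUE,
                   basis = basis, n_modes = 1, settings = NULL),
              class = "lvc_trajectory")
  }
  tgrid <- seq(0, 200, by = 0.5)

  ## identical sinusoids -> cohEX = 1
  ens_coh <- hand_ensemble(lapply(1:20, function(i)
    mk_traj(1.2 * sin(0.1 * tgrid))), basis)
  cd <- coherence_descriptors(ens_coh)
  expect_equal(cd$cohEX, 1, tolerance = 1e-10)

  ## same sinusoids with random phases -> cohEX below 0.1 at N = 200
  set.seed(55)
  ens_rnd <- hand_ensemble(lapply(1:200, function(i)
    mk_traj(1.2 * sin(0.1 * tgrid + runif(1, 0, 2 * pi)))), basis)
  cr <- coherence_descriptors(ens_rnd)
  expect_lt(cr$cohEX, 0.1)

  ## static ground-state Wigner ensemble -> shiftEX ~ 0, delta_sigma ~ 0
  set.seed(56)
  ens_null <- hand_ensemble(lapply(1:200, function(i)
    mk_traj(rep(rnorm(1, 0, sqrt(0.5)), length(tgrid)))), basis)
  cn <- coherence_descriptors(ens_null)
  expect_lt(cn$shiftEX, 0.2)
  expect_lt(abs(cn$delta_sigma), 0.2)
  expect_false(cn$important)

  ## window truncation warns
  expect_warning(coherence_descriptors(ens_coh, window = c(0, 1e5)),
                 "truncating")
})
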