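## Surface-hopping trajectory propagation in the diagonal
## (spin-orbit-including) representation: velocity-Verlet nuclear steps,
## local-diabatization electronic substeps, fewest-switches hops with
## full-velocity rescaling, energy-based decoherence.

#' Propagation settings
#'
#' @param dt_nuc nuclear time step (fs).
#' @param dt_el electronic substep (fs); must divide \code{dt_nuc}.
#' @param t_final total propagation time (fs); multiple of \code{dt_nuc}.
#' @param decoherence_C energy-based decoherence constant C (hartree);
#'   0.1 hartree is the standard choice.
#' @param frustrated policy for frustrated hops: \code{"keep"} (active
#'   state and velocities unchanged; default) or \code{"reverse"}
#'   (velocities reversed).
#' @param seed integer master seed.
#' @param record_stride store every k-th nuclear step (step 0 always).
#' @param frozen_nuclei if TRUE the nuclei are held fixed (no nuclear
#'   motion, zero kinetic energy; decoherence is skipped automatically).
#' @param hops if FALSE the stochastic hopping is disabled (coefficients
#'   still propagate; useful for testing).
#' @return object of class \code{propagation_settings}.
#' @export
propagation_settings <- function(dt_nuc = 0.5, dt_el = 0.02,
                                 t_final = 1000, decoherence_C = 0.1,
                                 frustrated = c("keep", "reverse"),
                                 seed = 1L, record_stride = 1L,
                                 frozen_nuclei = FALSE, hops = TRUE) {
  frustrated <- match.arg(frustrated)
  n_sub <- round(dt_nuc / dt_el)
  if (abs(n_sub * dt_el - dt_nuc) > 1e-9)
    stop("dt_el must divide dt_nuc")
  n_steps <- round(t_final / dt_nuc)
  if (abs(n_steps * dt_nuc - t_final) > 1e-9)
    stop("t_final must be a multiple of dt_nuc")
  structure(list(dt_nuc = dt_nuc, dt_el = dt_el, t_final = t_final,
                 n_sub = as.integer(n_sub), n_steps = as.integer(n_steps),
                 decoherence_C = decoherence_C, frustrated = frustrated,
                 seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 frozen_nuclei = frozen_nuclei, hops = hops),
            class = "propagation_settings")
}

#' Velocity rescaling at a surface hop
#'
#' On a hop from the active state to state j the full (mass-frequency-
#' scaled) velocity vector is rescaled by
#' \eqn{\sqrt{1 + (E_{active} - E_j)/E_{kin}}} so that total energy is
#' conserved.  If the radicand is negative the hop is frustrated: the
#' active state and velocities are kept (or the velocities reversed,
#' under the \code{"reverse"} policy).  A downward hop at zero kinetic
#' energy is accepted with velocities unchanged.
#'
#' @param active current active-state index.
#' @param target proposed state index.
#' @param E_diag diagonal-representation energies (eV).
#' @param P dimensionless momentum vector.
#' @param hw_ev per-mode energy quanta (eV), for the kinetic energy.
#' @param frustrated frustrated-hop policy.
#' @return list with \code{active}, \code{P}, \code{hopped},
#'   \code{frustrated}, \code{factor}.
#' @export
hop_and_rescale <- function(active, target, E_diag, P, hw_ev,
                            frustrated = "keep") {
  ekin <- sum(hw_ev * P^2) / 2
  gap <- E_diag[active] - E_diag[target]  # > 0 for downward hops
  if (ekin <= 0) {
    if (gap >= 0)
      return(list(active = target, P = P, hopped = TRUE,
                  frustrated = FALSE, factor = 1))
    return(list(active = active,
                P = if (frustrated == "reverse") -P else P,
                hopped = FALSE, frustrated = TRUE, factor = NA_real_))
  }
  rad <- 1 + gap / ekin
  if (rad < 0)
    return(list(active = active,
                P = if (frustrated == "reverse") -P else P,
                hopped = FALSE, frustrated = TRUE, factor = NA_real_))
  fac <- sqrt(rad)
  list(active = target, P = P * fac, hopped = TRUE, frustrated = FALSE,
       factor = fac)
}

#' Energy-based decoherence correction
#'
#' Damps every non-active coefficient by \eqn{\exp(-\Delta t/\tau_j)} with
#' \eqn{\tau_j = \frac{\hbar}{|E_j - E_{active}|}\left(1 +
#' \frac{C}{E_{kin}}\right)} and rescales the active coefficient so the
#' total norm is restored.  Degenerate states (\eqn{E_j = E_{active}})
#' are not damped; at non-positive kinetic energy the correction is
#' skipped entirely for that step.
#'
#' @param c_diag complex coefficient vector (diagonal basis).
#' @param active active-state index.
#' @param E_diag energies (eV).
#' @param ekin_ev kinetic energy (eV).
#' @param C decoherence constant (hartree).
#' @param dt time step (fs).
#' @return damped coefficient vector with unchanged norm.
#' @export
apply_decoherence <- function(c_diag, active, E_diag, ekin_ev, C = 0.1,
                              dt = 0.5) {
  if (ekin_ev <= 0) return(c_diag)
  norm0 <- sum(Mod(c_diag)^2)
  gaps <- abs(E_diag - E_diag[active])
  C_ev <- C * lvc_units$ev_per_hartree
  fac <- ifelse(gaps > 0,
                exp(-dt * gaps / (lvc_units$hbar_ev_fs *
                                    (1 + C_ev / ekin_ev))),
                1)
  fac[active] <- 1
  cc <- c_diag * fac
  rest <- sum(Mod(cc[-active])^2)
  pa <- Mod(cc[active])^2
  if (pa > 0) {
    cc[active] <- cc[active] * sqrt(max(norm0 - rest, 0) / pa)
  }
  cc
}

## full diag->diabatic transform at one step: columns are the diagonal
## states expressed in the spin-expanded diabatic basis
diag_in_diabatic <- function(basis, U_sf, U_diag) {
  spin_expand_transform(basis, U_sf) %*% U_diag
}

#' Propagate one surface-hopping trajectory
#'
#' Runs fewest-switches surface hopping on the LVC surfaces: nuclear
#' velocity-Verlet on the active diagonal state's gradient (diagonal
#' approximation: MCH Hellmann-Feynman gradients weighted by
#' \eqn{|U^{diag}|^2}), electronic coefficients advanced each substep by
#' the local-diabatization propagator built from time overlaps and the
#' linearly interpolated Hamiltonian, stochastic hops from the relative
#' population loss of the active state distributed over gaining states,
#' full-velocity rescaling at hops, and energy-based decoherence each
#' nuclear step.  The initially selected MCH state is mapped to the
#' diagonal state of maximum overlap.
#'
#' @param model an \code{lvc_model}.
#' @param Q0,P0 initial mode coordinates and momenta (dimensionless).
#' @param init_state initial spin-free MCH state index (singlets first,
#'   ground state = 1).
#' @param settings a \code{propagation_settings}.
#' @param rng_seed optional per-trajectory seed overriding
#'   \code{settings$seed}.
#' @param init_coeff \code{"diag"} (default) sets the coefficient vector
#'   to the pure diagonal state of maximum overlap with the selected MCH
#'   state; \code{"mch"} sets it to the selected MCH state expressed in
#'   the diagonal basis (a coherent superposition), the appropriate
#'   choice when comparing coefficient populations against exact quantum
#'   references.
#' @return object of class \code{lvc_trajectory}; see Details in the
#'   package vignette for the stored per-step record.
#' @export
propagate_trajectory <- function(model, Q0, P0, init_state, settings,
                                 rng_seed = NULL,
                                 init_coeff = c("diag", "mch")) {
  init_coeff <- match.arg(init_coeff)
  stopifnot(inherits(model, "lvc_model"),
            inherits(settings, "propagation_settings"))
  p <- model$parameters
  basis <- p$basis
  n_sf <- basis$n_sf
  D <- basis$dim
  nf <- p$n_modes
  if (length(Q0) != nf || length(P0) != nf)
    stop("Q0/P0 must have length F")
  if (init_state < 1 || init_state > n_sf)
    stop("init_state outside the truncated model")
  set.seed(if (is.null(rng_seed)) settings$seed else as.integer(rng_seed))

  hbar <- lvc_units$hbar_ev_fs
  hw <- mode_quantum_ev(model$reference)
  dt <- settings$dt_nuc
  n_steps <- settings$n_steps
  stride <- settings$record_stride
  rec_idx <- unique(c(seq(0L, n_steps, by = stride), n_steps))
  n_rec <- length(rec_idx)
  frozen <- settings$frozen_nuclei

  ## storage
  times <- rec_idx * dt
  Q_rec <- matrix(NA_real_, n_rec, nf)
  P_rec <- matrix(NA_real_, n_rec, nf)
  act_rec <- integer(n_rec)
  Emch_rec <- matrix(NA_real_, n_rec, n_sf)
  Ediag_rec <- matrix(NA_real_, n_rec, D)
  c_rec <- matrix(NA_complex_, n_rec, D)
  Usf_rec <- array(NA_real_, c(n_sf, n_sf, n_rec))
  Udiag_rec <- array(NA_complex_, c(D, D, n_rec))
  ekin_rec <- numeric(n_rec)
  etot_rec <- numeric(n_rec)
  hops <- list()

  ## electronic structure at one geometry
  eval_step <- function(Q, U_sf_prev, U_diag_prev) {
    pot <- evaluate_potential(model, Q, derivatives = !frozen)
    ad <- adiabatize(pot, basis, U_prev = U_sf_prev)
    soc_mch <- transform_properties(ad$U, basis, soc = p$soc)$soc_mch
    dg <- build_diagonal(ad$E_mch, soc_mch, basis, U_prev = U_diag_prev)
    g_mch <- NULL
    if (!frozen) {
      U <- ad$U
      g_mch <- matrix(0, n_sf, nf)
      for (i in seq_len(nf))
        g_mch[, i] <- colSums(U * (pot$dV[, , i] %*% U))
    }
    list(pot = pot, ad = ad, dg = dg, g_mch = g_mch)
  }
  ## diagonal-state gradient (diagonal approximation)
  map_exp <- spin_expansion_map(basis)
  grad_active <- function(st, active) {
    wts_exp <- Mod(st$dg$U_diag[, active])^2
    wts <- vapply(seq_len(n_sf), function(nn)
      sum(wts_exp[map_exp == nn]), numeric(1))
    as.numeric(wts %*% st$g_mch)
  }

  Q <- as.numeric(Q0)
  P <- if (frozen) numeric(nf) else as.numeric(P0)
  st <- eval_step(Q, NULL, NULL)
  active <- which.max(Mod(st$dg$U_diag[init_state, ]))
  if (init_coeff == "diag") {
    c_diag <- rep(0 + 0i, D)
    c_diag[active] <- 1 + 0i
  } else {
    e_mch <- rep(0 + 0i, D)
    e_mch[init_state] <- 1 + 0i
    c_diag <- as.complex(Conj(t(st$dg$U_diag)) %*% e_mch)
  }

  ekin <- sum(hw * P^2) / 2
  etot0 <- st$dg$E_diag[active] + ekin

  record <- function(slot, step_idx) {
    Q_rec[slot, ] <<- Q
    P_rec[slot, ] <<- P
    act_rec[slot] <<- active
    Emch_rec[slot, ] <<- st$ad$E_mch
    Ediag_rec[slot, ] <<- st$dg$E_diag
    c_rec[slot, ] <<- c_diag
    Usf_rec[, , slot] <<- st$ad$U
    Udiag_rec[, , slot] <<- st$dg$U_diag
    ekin_rec[slot] <<- ekin
    etot_rec[slot] <<- st$dg$E_diag[active] + ekin
  }
  slot <- 1L
  record(slot, 0L)

  g <- if (frozen) NULL else grad_active(st, active)
  for (step in seq_len(n_steps)) {
    E0 <- st$dg$E_diag
    W_prev <- diag_in_diabatic(basis, st$ad$U, st$dg$U_diag)
    if (!frozen) {
      P_half <- P - (dt / 2) * g / hbar
      Q <- Q + dt * (hw / hbar) * P_half
      st_new <- eval_step(Q, st$ad$U, st$dg$U_diag)
      g_new <- grad_active(st_new, active)
      P <- P_half - (dt / 2) * g_new / hbar
    } else {
      st_new <- eval_step(Q, st$ad$U, st$dg$U_diag)
    }
    if (any(!is.finite(Q)) || any(!is.finite(P)))
      stop(sprintf("non-finite coordinates at step %d (t = %.2f fs)",
                   step, step * dt))
    W_curr <- diag_in_diabatic(basis, st_new$ad$U, st_new$dg$U_diag)
    S <- time_overlap(W_prev, W_curr, step = step, align_phases = FALSE)
    R <- ld_propagator_cpp(E0, S, st_new$dg$E_diag, dt, settings$n_sub)
    c_old <- c_diag
    c_diag <- as.complex(R %*% c_old)

    ## fewest-switches hop from the active-state population balance
    if (settings$hops) {
      pa_old <- Mod(c_old[active])^2
      pa_new <- Mod(c_diag[active])^2
      if (pa_old > 0) {
        p_leave <- max(0, (pa_old - pa_new) / pa_old)
        gains <- pmax(0, Mod(c_diag)^2 - Mod(c_old)^2)
        gains[active] <- 0
        tot <- sum(gains)
        if (p_leave > 0 && tot > 0) {
          probs <- p_leave * gains / tot
          r <- stats::runif(1)
          cum <- cumsum(probs)
          tgt <- which(r < cum)[1]
          if (!is.na(tgt)) {
            hr <- hop_and_rescale(active, tgt, st_new$dg$E_diag, P, hw,
                                  settings$frustrated)
            hops[[length(hops) + 1L]] <- data.frame(
              step = step, t = step * dt, from = active, to = tgt,
              accepted = hr$hopped, frustrated = hr$frustrated)
            if (hr$hopped) {
              active <- hr$active
              P <- hr$P
              if (!frozen) g_new <- grad_active(st_new, active)
            }
          }
        }
      }
    }
    ekin <- sum(hw * P^2) / 2
    if (!frozen)
      c_diag <- apply_decoherence(c_diag, active, st_new$dg$E_diag, ekin,
                                  settings$decoherence_C, dt)
    st <- st_new
    if (!frozen) g <- g_new
    if (step %in% rec_idx) {
      slot <- slot + 1L
      record(slot, step)
    }
  }

  ## energy-conservation audit: worst drift over any 100-step window
  drift <- 0
  if (n_rec > 1L) {
    w <- max(1L, round(100 / stride))
    for (i in seq_len(n_rec - 1L)) {
      j <- min(n_rec, i + w)
      drift <- max(drift, abs(etot_rec[j] - etot_rec[i]))
    }
  }
  hops_df <- if (length(hops)) do.call(rbind, hops) else
    data.frame(step = integer(), t = numeric(), from = integer(),
               to = integer(), accepted = logical(), frustrated = logical())
  valid <- drift <= 0.05  # velocity rescaling keeps E_tot constant at hops
  structure(
    list(times = times, Q = Q_rec, P = P_rec, active = act_rec,
         E_mch = Emch_rec, E_diag = Ediag_rec, c_diag = c_rec,
         U_sf = Usf_rec, U_diag = Udiag_rec, ekin = ekin_rec,
         etot = etot_rec, hops = hops_df, energy_drift = drift,
         valid = valid, init_state = init_state,
         basis = basis, n_modes = nf, settings = settings),
    class = "lvc_trajectory")
}

#' @export
print.lvc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lvc_trajectory> %.1f fs, %d recorded steps, %d hops, drift %.2e eV\n",
    max(x$times), length(x$times), sum(x$hops$accepted), x$energy_drift))
  invisible(x)
}

#' Propagate an ensemble of trajectories
#'
#' Propagates every selected initial condition with an independent RNG
#' stream derived from the master seed.  Failed trajectories are recorded
#' with their error message rather than silently dropped.
#'
#' @param model an \code{lvc_model}.
#' @param selections data.frame from \code{\link{select_initial_states}}
#'   (columns \code{sample_id}, \code{state}).
#' @param samples Wigner samples (from \code{\link{sample_wigner}})
#'   supplying Q0/P0 per \code{sample_id}.
#' @param settings a \code{propagation_settings}.
#' @param init_coeff initial-coefficient convention, see
#'   \code{\link{propagate_trajectory}}.
#' @return object of class \code{lvc_ensemble}: trajectories plus
#'   failure records and metadata.
#' @export
run_ensemble <- function(model, selections, samples, settings,
                         init_coeff = "diag") {
  if (nrow(selections) == 0L) stop("selections must be non-empty")
  n <- nrow(selections)
  trajs <- vector("list", n)
  failures <- list()
  for (k in seq_len(n)) {
    sid <- selections$sample_id[k]
    seed_k <- (as.double(settings$seed) * 48271 + 7919 * k) %% 2147483647
    seed_k <- as.integer(seed_k) + 1L
    res <- tryCatch(
      propagate_trajectory(model, samples$Q[sid, ], samples$P[sid, ],
                           selections$state[k], settings,
                           rng_seed = seed_k, init_coeff = init_coeff),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(index = k, sample_id = sid,
                   message = conditionMessage(res))
      trajs[k] <- list(NULL)
    } else {
      res$sample_id <- sid
      res$traj_seed <- seed_k
      trajs[[k]] <- res
    }
  }
  structure(
    list(trajectories = trajs,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         selections = selections, settings = settings,
         basis = model$parameters$basis, n_modes = model$reference$n_modes,
         seed = settings$seed),
    class = "lvc_ensemble")
}

#' @export
print.lvc_ensemble <- function(x, ...) {
  ok <- sum(!vapply(x$trajectories, is.null, logical(1)))
  cat(sprintf("<lvc_ensemble> %d trajectories (%d failed), %.1f fs\n",
              length(x$trajectories), length(x$trajectories) - ok,
              x$settings$t_final))
  invisible(x)
}
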