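## Ensemble analysis: populations in three representations, CT-character
## evolution, hot/cold biexponential kinetics, normal-mode coherence
## descriptors.

live_trajectories <- function(ensemble) {
  Filter(Negate(is.null), ensemble$trajectories)
}

## Transform one trajectory's stored diagonal-basis data to a
## representation ("diagonal", "mch", "diabatic") at step slot k.
## Returns the unitary A with c_rep = A %*% c_diag.
rep_transform <- function(traj, basis, rep, k) {
  switch(rep,
         diagonal = diag(basis$dim) + 0i,
         mch = traj$U_diag[, , k],
         diabatic = spin_expand_transform(basis, traj$U_sf[, , k]) %*%
           traj$U_diag[, , k],
         stop("unknown representation: ", rep))
}

#' Electronic population time series
#'
#' Ensemble-averaged populations in the diagonal, MCH or diabatic
#' representation with one of three estimators: \code{"active"} counts the
#' active diagonal state of each trajectory, mapped to the representation
#' by \eqn{|A|^2}; \code{"coefficient"} averages \eqn{|A c|^2};
#' \code{"mixed"} (default) builds the per-trajectory density matrix with
#' the active-state populations on the diagonal and the coherences of the
#' coefficient vector off-diagonal, transforms it, and averages (the
#' standard combination of surface populations and coherences).
#'
#' @param ensemble an \code{lvc_ensemble}.
#' @param representation \code{"diagonal"}, \code{"mch"} or
#'   \code{"diabatic"}.
#' @param estimator \code{"mixed"}, \code{"active"} or
#'   \code{"coefficient"}.
#' @param collapse_ms sum the three MS components of each triplet
#'   (diabatic/MCH representations) into one column (default TRUE).
#' @return data.frame: \code{time} plus one population column per state.
#'   Small negative dips of the mixed estimator (>= -1e-3) are clipped to
#'   zero with a warning attribute.
#' @export
populations <- function(ensemble,
                        representation = c("mch", "diagonal", "diabatic"),
                        estimator = c("mixed", "active", "coefficient"),
                        collapse_ms = TRUE) {
  representation <- match.arg(representation)
  estimator <- match.arg(estimator)
  basis <- ensemble$basis
  D <- basis$dim
  trajs <- live_trajectories(ensemble)
  if (!length(trajs)) stop("ensemble contains no valid trajectories")
  nt_steps <- length(trajs[[1]]$times)
  pop <- matrix(0, nt_steps, D)
  clipped <- FALSE
  for (traj in trajs) {
    for (k in seq_len(nt_steps)) {
      A <- rep_transform(traj, basis, representation, k)
      cvec <- traj$c_diag[k, ]
      a <- traj$active[k]
      pk <- switch(estimator,
        active = Mod(A[, a])^2,
        coefficient = Mod(A %*% cvec)^2,
        mixed = {
          e_a <- numeric(D); e_a[a] <- 1
          Mod(A %*% cvec)^2 + Mod(A)^2 %*% (e_a - Mod(cvec)^2)
        })
      pop[k, ] <- pop[k, ] + as.numeric(pk)
    }
  }
  pop <- pop / length(trajs)
  if (any(pop < 0)) {
    if (min(pop) < -1e-3)
      warning(sprintf("mixed-estimator population dips to %.3g", min(pop)))
    clipped <- TRUE
    pop[pop < 0] <- 0
    pop <- pop / rowSums(pop)  # restore the exact partition after clipping
  }
  labels <- spin_expansion_labels(basis)
  if (collapse_ms && representation != "diagonal") {
    map <- spin_expansion_map(basis)
    agg <- matrix(0, nt_steps, basis$n_sf)
    for (nn in seq_len(basis$n_sf))
      agg[, nn] <- rowSums(pop[, map == nn, drop = FALSE])
    pop <- agg
    labels <- basis$labels
  } else if (representation == "diagonal") {
    labels <- paste0("diag", seq_len(D))
  }
  out <- data.frame(time = trajs[[1]]$times)
  out[labels] <- pop
  attr(out, "representation") <- representation
  attr(out, "estimator") <- estimator
  attr(out, "clipped") <- clipped
  out
}

#' Total singlet and triplet populations
#'
#' Sums the per-state populations of \code{\link{populations}} over the
#' two multiplicities (MCH representation by default), the input of the
#' hot/cold kinetic fit.
#'
#' @inheritParams populations
#' @return data.frame with \code{time}, \code{singlet}, \code{triplet}.
#' @export
multiplicity_populations <- function(ensemble, representation = "mch",
                                     estimator = "mixed") {
  pp <- populations(ensemble, representation, estimator,
                    collapse_ms = TRUE)
  basis <- ensemble$basis
  mult <- if (representation == "diagonal")
    stop("multiplicity is not defined for diagonal states") else
      basis$multiplicity
  m <- as.matrix(pp[, -1L, drop = FALSE])
  data.frame(time = pp$time,
             singlet = rowSums(m[, mult == 1L, drop = FALSE]),
             triplet = rowSums(m[, mult == 3L, drop = FALSE]))
}

## per-trajectory singlet indicator/population matrix (time x trajectory),
## used by the kinetics bootstrap
singlet_matrix <- function(ensemble, estimator = "mixed") {
  basis <- ensemble$basis
  trajs <- live_trajectories(ensemble)
  map <- spin_expansion_map(basis)
  s_cols <- basis$multiplicity[map] == 1L
  vapply(trajs, function(traj) {
    vapply(seq_along(traj$times), function(k) {
      A <- rep_transform(traj, basis, "mch", k)
      cvec <- traj$c_diag[k, ]
      a <- traj$active[k]
      e_a <- numeric(basis$dim); e_a[a] <- 1
      pk <- switch(estimator,
        active = Mod(A[, a])^2,
        coefficient = Mod(A %*% cvec)^2,
        mixed = Mod(A %*% cvec)^2 + Mod(A)^2 %*% (e_a - Mod(cvec)^2))
      sum(pmax(as.numeric(pk), 0)[s_cols])
    }, numeric(1))
  }, numeric(length(trajs[[1]]$times)))
}

#' Charge-transfer character evolution
#'
#' Transforms each trajectory's diabatic coefficient vector with the
#' CT-number table, \eqn{\Omega^{el}_{AB}(t) = \sum_{n,m} c^*_n c_m
#' \Omega^{(n,m)}_{AB}}, and averages over the ensemble, yielding the
#' time-resolved fragment-pair CT composition of the propagated
#' wavefunction (and its aggregation into the character classes).
#'
#' @param ensemble an \code{lvc_ensemble}.
#' @param ct_table a \code{ct_number_table}; if its transition (off-
#'   diagonal) entries are all zero a diagonal-only fallback warning is
#'   issued.
#' @param subset optional logical/integer index over valid trajectories.
#' @return data.frame with \code{time}, one \code{omega_<A>_<B>} column
#'   per fragment pair with any weight, and one \code{class_<X>} column
#'   per character class.
#' @export
ct_evolution <- function(ensemble, ct_table, subset = NULL) {
  stopifnot(inherits(ct_table, "ct_number_table"))
  basis <- ensemble$basis
  trajs <- live_trajectories(ensemble)
  if (!is.null(subset)) trajs <- trajs[subset]
  if (!length(trajs)) stop("no trajectories selected")
  off <- ct_table$omega
  for (n in seq_len(ct_table$n_states)) off[n, n, , ] <- 0
  if (all(off == 0))
    warning("CT table has no transition entries; cross terms vanish ",
            "(diagonal-only fallback)")
  nfr <- length(ct_table$fragments)
  nt_steps <- length(trajs[[1]]$times)
  ## precompute spin-expanded pair matrices
  pair_mats <- vector("list", nfr * nfr)
  for (a in seq_len(nfr)) for (b in seq_len(nfr))
    pair_mats[[(a - 1L) * nfr + b]] <-
      ct_pair_matrix_expanded(basis, ct_table, a, b)
  acc <- matrix(0, nt_steps, nfr * nfr)
  for (traj in trajs) {
    for (k in seq_len(nt_steps)) {
      A <- rep_transform(traj, basis, "diabatic", k)
      cd <- as.complex(A %*% traj$c_diag[k, ])
      for (ab in seq_len(nfr * nfr)) {
        v <- Conj(cd) %*% pair_mats[[ab]] %*% cd
        acc[k, ab] <- acc[k, ab] + check_real(v)
      }
    }
  }
  acc <- acc / length(trajs)
  ## column names matching the (a-1)*nfr + b pair layout
  cn <- character(nfr * nfr)
  for (a in seq_len(nfr)) for (b in seq_len(nfr))
    cn[(a - 1L) * nfr + b] <- paste0("omega_", ct_table$fragments[a], "_",
                                     ct_table$fragments[b])
  colnames(acc) <- cn
  out <- data.frame(time = trajs[[1]]$times)
  keep <- colSums(abs(acc)) > 0
  out <- cbind(out, as.data.frame(acc[, keep, drop = FALSE]))
  ## class aggregation
  defs <- ct_class_definitions()
  for (k in seq_len(nrow(defs))) {
    a <- match(defs$hole[k], ct_table$fragments)
    b <- match(defs$elec[k], ct_table$fragments)
    if (is.na(a) || is.na(b)) next
    out[[paste0("class_", defs$class[k])]] <- acc[, (a - 1L) * nfr + b]
  }
  out
}

#' Final-frame CT character split of an ensemble
#'
#' Classifies each trajectory by its CS fraction at a chosen frame
#' (default: the final frame, threshold 50%) and returns the trajectory
#' indices of the two classes, for sub-ensemble analyses.
#'
#' @param ensemble an \code{lvc_ensemble}.
#' @param ct_table a \code{ct_number_table}.
#' @param threshold CS-fraction threshold (default 0.5).
#' @param frame \code{"final"} or \code{"initial"}.
#' @return list with indices \code{cs} and \code{other} and the per-
#'   trajectory CS fractions.
#' @export
split_by_cs_character <- function(ensemble, ct_table, threshold = 0.5,
                                  frame = c("final", "initial")) {
  frame <- match.arg(frame)
  basis <- ensemble$basis
  trajs <- live_trajectories(ensemble)
  a <- match("Trp", ct_table$fragments)
  b <- match("Dmp", ct_table$fragments)
  if (is.na(a) || is.na(b)) stop("CT table lacks Trp/Dmp fragments")
  M_cs <- ct_pair_matrix_expanded(basis, ct_table, a, b)
  frac <- vapply(trajs, function(traj) {
    k <- if (frame == "final") length(traj$times) else 1L
    A <- rep_transform(traj, basis, "diabatic", k)
    cd <- as.complex(A %*% traj$c_diag[k, ])
    tot <- 0
    for (aa in seq_along(ct_table$fragments))
      for (bb in seq_along(ct_table$fragments))
        tot <- tot + check_real(Conj(cd) %*%
          ct_pair_matrix_expanded(basis, ct_table, aa, bb) %*% cd)
    cs <- check_real(Conj(cd) %*% M_cs %*% cd)
    if (tot > 0) cs / tot else 0
  }, numeric(1))
  list(cs = which(frac > threshold), other = which(frac <= threshold),
       fraction = frac)
}

## Biexponential of the hot/cold kinetic model
biexp_model <- function(t, R_fast, tau_fast, tau_slow) {
  R_fast * exp(-t / tau_fast) + (1 - R_fast) * exp(-t / tau_slow)
}

## (R_fast, tau_fast, tau_slow) <-> (tau1, tau2, tauc) identities
kinetic_identities <- function(R_fast, tau_fast, tau_slow) {
  k <- 1 / tau_fast
  b <- 1 / tau_slow
  a <- b + R_fast * (k - b)
  cc <- k - a
  list(tau1 = 1 / a, tau2 = tau_slow,
       tauc = if (cc > 0) 1 / cc else Inf)
}

kinetic_identities_inverse <- function(tau1, tau2, tauc) {
  a <- 1 / tau1; b <- 1 / tau2; cc <- if (is.finite(tauc)) 1 / tauc else 0
  list(R_fast = (a - b) / (cc + a - b), tau_fast = 1 / (a + cc),
       tau_slow = tau2)
}

fit_biexp_once <- function(times, S) {
  sse <- function(par) {
    R <- stats::plogis(par[1])
    tf <- exp(par[2]); ts <- tf * (1 + exp(par[3]))
    sum((S - biexp_model(times, R, tf, ts))^2)
  }
  tmax <- max(times[times > 0], 1)
  starts <- list(c(0.4, log(tmax / 50), log(9)),
                 c(1.0, log(tmax / 100), log(20)),
                 c(-1.0, log(tmax / 20), log(4)))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(stats::optim(s0, sse, method = "Nelder-Mead",
                                 control = list(maxit = 4000,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || best$convergence != 0)
    stop(sprintf("kinetic fit did not converge (residual %.3g)",
                 if (is.null(best)) NA_real_ else best$value))
  R <- stats::plogis(best$par[1])
  tf <- exp(best$par[2]); ts <- tf * (1 + exp(best$par[3]))
  list(R_fast = R, tau_fast = tf, tau_slow = ts, sse = best$value)
}

#' Fit the hot/cold biexponential kinetic model
#'
#' Fits the total singlet population to
#' \eqn{S(t) = R_{fast} e^{-t/\tau_{fast}} + (1-R_{fast})
#' e^{-t/\tau_{slow}}}, the closed-form solution of the three-species
#' kinetic scheme in which a "hot" singlet subpopulation undergoes fast
#' intersystem crossing (\eqn{\tau_1}) or cools (\eqn{\tau_c}) into a
#' "cold" singlet that crosses slowly (\eqn{\tau_2}).  The rate constants
#' are recovered from the fit parameters through
#' \eqn{R_{fast} = (1/\tau_1 - 1/\tau_2)/(1/\tau_c + 1/\tau_1 -
#' 1/\tau_2)}, \eqn{\tau_{fast} = 1/(1/\tau_1 + 1/\tau_c)},
#' \eqn{\tau_{slow} = \tau_2}.  Uncertainties come from a trajectory
#' bootstrap (resample trajectories, refit).
#'
#' @param times time grid (fs).
#' @param singlet total singlet population (S(0) close to 1).
#' @param traj_matrix optional per-trajectory singlet matrix
#'   (time x trajectory) enabling the bootstrap; see
#'   \code{\link{fit_kinetics_ensemble}}.
#' @param n_boot bootstrap replicates (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return object of class \code{kinetic_fit}: tau1, tau2, tauc, R_fast,
#'   tau_fast, tau_slow (fs), confidence half-widths \code{ci} (95%,
#'   bootstrap), and the residual.
#' @export
fit_kinetics <- function(times, singlet, traj_matrix = NULL, n_boot = 100L,
                         seed = 1L) {
  if (abs(singlet[1] - 1) > 0.2)
    warning("singlet population does not start near 1")
  fit <- fit_biexp_once(times, singlet)
  der <- kinetic_identities(fit$R_fast, fit$tau_fast, fit$tau_slow)
  ci <- NULL
  if (!is.null(traj_matrix) && n_boot > 0L) {
    set.seed(as.integer(seed))
    n <- ncol(traj_matrix)
    boots <- matrix(NA_real_, n_boot, 3L,
                    dimnames = list(NULL, c("R_fast", "tau_fast",
                                            "tau_slow")))
    for (bidx in seq_len(n_boot)) {
      cols <- sample.int(n, n, replace = TRUE)
      Sb <- rowMeans(traj_matrix[, cols, drop = FALSE])
      fb <- tryCatch(fit_biexp_once(times, Sb), error = function(e) NULL)
      if (!is.null(fb))
        boots[bidx, ] <- c(fb$R_fast, fb$tau_fast, fb$tau_slow)
    }
    half <- function(v) diff(stats::quantile(v, c(0.025, 0.975),
                                             na.rm = TRUE)) / 2
    ci <- c(R_fast = half(boots[, 1]), tau_fast = half(boots[, 2]),
            tau_slow = half(boots[, 3]))
    names(ci) <- c("R_fast", "tau_fast", "tau_slow")
  }
  flagged <- fit$R_fast < 0 || fit$R_fast > 1
  structure(list(R_fast = fit$R_fast, tau_fast = fit$tau_fast,
                 tau_slow = fit$tau_slow, tau1 = der$tau1,
                 tau2 = der$tau2, tauc = der$tauc, sse = fit$sse,
                 ci = ci, flagged = flagged),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> R_fast = %.3f, tau_fast = %.1f fs, tau_slow = %.1f fs\n",
    x$R_fast, x$tau_fast, x$tau_slow))
  cat(sprintf("  tau1 = %.1f fs, tau2 = %.1f fs, tauc = %.1f fs\n",
              x$tau1, x$tau2, x$tauc))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap half-widths: R %.3f, fast %.1f, slow %.1f\n",
                x$ci["R_fast"], x$ci["tau_fast"], x$ci["tau_slow"]))
  invisible(x)
}

#' Kinetic fit of a propagated ensemble
#'
#' Convenience wrapper: extracts the total singlet population (MCH
#' representation, chosen estimator) and the per-trajectory singlet
#' matrix for the bootstrap, then calls \code{\link{fit_kinetics}}.
#'
#' @param ensemble an \code{lvc_ensemble}.
#' @param estimator population estimator.
#' @param n_boot,seed bootstrap controls.
#' @return a \code{kinetic_fit}.
#' @export
fit_kinetics_ensemble <- function(ensemble, estimator = "mixed",
                                  n_boot = 100L, seed = 1L) {
  sm <- singlet_matrix(ensemble, estimator)
  trajs <- live_trajectories(ensemble)
  fit_kinetics(trajs[[1]]$times, rowMeans(sm), traj_matrix = sm,
               n_boot = n_boot, seed = seed)
}

#' Normal-mode coherence descriptors
#'
#' Per-mode descriptors of the ensemble's nuclear motion over a time
#' window, relative to the ground-state width \eqn{\sigma_0 = 1/\sqrt 2}:
#' \describe{
#' \item{shiftEX}{absolute time-average of the ensemble-mean coordinate,
#'   over \eqn{\sigma_0}: how far the excited-state minimum is displaced.}
#' \item{cohEX}{standard deviation over time of the ensemble-mean trace
#'   divided by the trajectory-average of each trajectory's own standard
#'   deviation over time, clipped to [0, 1]: 1 for perfectly in-phase
#'   motion, near 0 for random phases.}
#' \item{delta_sigma}{relative change of the time-averaged ensemble
#'   width: positive when the distribution spreads (e.g. into several
#'   near-isoenergetic minima).}
#' }
#' A mode is flagged important when at least two descriptors exceed their
#' thresholds.
#'
#' @param ensemble an \code{lvc_ensemble} (>= 2 trajectories).
#' @param window c(t0, t1) analysis window (fs); truncated with a warning
#'   if longer than the archive.
#' @param thresholds named vector with elements \code{shift}, \code{coh},
#'   \code{dsigma}.
#' @return data.frame with one row per mode: \code{mode}, \code{shiftEX},
#'   \code{cohEX}, \code{delta_sigma}, \code{important}.
#' @export
coherence_descriptors <- function(ensemble, window = NULL,
                                  thresholds = c(shift = 0.25, coh = 0.3,
                                                 dsigma = 0.15)) {
  trajs <- live_trajectories(ensemble)
  if (length(trajs) < 2L) stop("coherence analysis needs >= 2 trajectories")
  times <- trajs[[1]]$times
  if (is.null(window)) window <- range(times)
  if (window[2] > max(times)) {
    warning("window longer than archive; truncating")
    window[2] <- max(times)
  }
  sel <- which(times >= window[1] & times <= window[2])
  nf <- ensemble$n_modes
  sigma0 <- 1 / sqrt(2)
  n_tr <- length(trajs)
  out <- data.frame(mode = seq_len(nf), shiftEX = NA_real_,
                    cohEX = NA_real_, delta_sigma = NA_real_)
  for (i in seq_len(nf)) {
    X <- vapply(trajs, function(tr) tr$Q[sel, i], numeric(length(sel)))
    mean_trace <- rowMeans(X)          # ensemble mean at each time
    out$shiftEX[i] <- abs(mean(mean_trace)) / sigma0
    sd_of_mean <- stats::sd(mean_trace)
    mean_of_sd <- mean(apply(X, 2L, stats::sd))
    out$cohEX[i] <- if (mean_of_sd > 0)
      min(max(sd_of_mean / mean_of_sd, 0), 1) else 0
    ens_sd <- apply(X, 1L, stats::sd) * sqrt((n_tr - 1) / n_tr)
    out$delta_sigma[i] <- (mean(ens_sd) - sigma0) / sigma0
  }
  n_exceed <- (out$shiftEX > thresholds[["shift"]]) +
    (out$cohEX > thresholds[["coh"]]) +
    (abs(out$delta_sigma) > thresholds[["dsigma"]])
  out$important <- n_exceed >= 2L
  attr(out, "thresholds") <- thresholds
  attr(out, "window") <- window
  out
}
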