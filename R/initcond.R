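## Initial conditions: ground-state Wigner sampling, vertical excitations,
## absorption spectrum with CT decomposition, stochastic initial-state
## selection in an excitation window.

#' Sample the ground-state Wigner distribution
#'
#' Draws phase-space points from the Wigner distribution of the harmonic
#' ground state defined by \eqn{V_0}: in the dimensionless
#' mass-frequency-scaled convention every \eqn{Q_i} and conjugate
#' \eqn{P_i} is an independent Gaussian with mean 0 and variance 1/2
#' (zero temperature, pure vibrational ground state).
#'
#' @param reference a \code{harmonic_reference}.
#' @param n number of samples (>= 1).
#' @param seed integer seed; the same seed yields bit-identical samples.
#' @return list with matrices \code{Q} and \code{P} (n x F) and
#'   \code{seed_id = seq_len(n)}.
#' @export
sample_wigner <- function(reference, n, seed = 1L) {
  stopifnot(inherits(reference, "harmonic_reference"), n >= 1)
  nf <- reference$n_modes
  set.seed(as.integer(seed))
  Q <- matrix(stats::rnorm(n * nf, sd = sqrt(0.5)), n, nf)
  P <- matrix(stats::rnorm(n * nf, sd = sqrt(0.5)), n, nf)
  list(Q = Q, P = P, seed_id = seq_len(n))
}

#' Vertical excitation at one geometry
#'
#' Evaluates the spin-free MCH states at the given mode coordinates:
#' excitation energies relative to the lowest singlet, oscillator
#' strengths \eqn{f_n = (2/3)\,\Delta E\, |\mu_{0n}|^2} (atomic units)
#' from the MCH-transformed dipole matrices, and fragment CT-class
#' fractions of each MCH state obtained by applying the CT-number
#' transform to its diabatic expansion coefficients (normalized by the
#' state's total CT weight).
#'
#' @param model an \code{lvc_model} (CT fractions require its
#'   \code{ct_table}).
#' @param Q mode coordinates (dimensionless), length F.
#' @return data.frame with one row per spin-free state: \code{state},
#'   \code{label}, \code{multiplicity}, \code{energy} (eV, relative to
#'   the lowest singlet), \code{f_osc}, and one \code{frac_<class>}
#'   column per CT class present.
#' @export
vertical_excitation <- function(model, Q) {
  p <- model$parameters
  basis <- p$basis
  pot <- evaluate_potential(model, Q, derivatives = FALSE)
  ad <- adiabatize(pot, basis)
  s_idx <- which(basis$multiplicity == 1L)
  e0 <- min(ad$E_mch[s_idx])
  dE <- ad$E_mch - e0

  tp <- transform_properties(ad$U, basis, dipoles = p$dipoles)
  mu2 <- Reduce(`+`, lapply(tp$dipoles_mch, function(m) m[1L, ]^2))
  f <- (2 / 3) * ev2au(dE) * mu2
  f[1L] <- 0

  out <- data.frame(state = seq_len(basis$n_sf),
                    label = basis$labels,
                    multiplicity = basis$multiplicity,
                    energy = dE, f_osc = f,
                    stringsAsFactors = FALSE)
  ct <- model$ct_table
  if (!is.null(ct)) {
    defs <- ct_class_definitions()
    classes <- defs$class
    frac <- matrix(0, basis$n_sf, length(classes),
                   dimnames = list(NULL, classes))
    for (nidx in seq_len(basis$n_sf)) {
      w <- wavefunction_ct_numbers(ad$U[, nidx], ct, basis)
      tot <- sum(w)
      if (tot > 0) {
        for (k in seq_along(classes)) {
          i <- match(defs$hole[k], ct$fragments)
          j <- match(defs$elec[k], ct$fragments)
          if (!is.na(i) && !is.na(j)) frac[nidx, k] <- w[i, j] / tot
        }
      }
    }
    colnames(frac) <- paste0("frac_", classes)
    out <- cbind(out, as.data.frame(frac))
  }
  out
}

#' Vertical excitations over a Wigner sample batch
#'
#' Applies \code{\link{vertical_excitation}} to every sampled geometry and
#' stacks the records with a \code{sample_id} column.
#'
#' @param model an \code{lvc_model}.
#' @param samples result of \code{\link{sample_wigner}}.
#' @return data.frame of stacked excitation records.
#' @export
vertical_excitation_batch <- function(model, samples) {
  recs <- lapply(seq_len(nrow(samples$Q)), function(k) {
    r <- vertical_excitation(model, samples$Q[k, ])
    cbind(sample_id = samples$seed_id[k], r)
  })
  do.call(rbind, recs)
}

#' Absorption spectrum with charge-transfer decomposition
#'
#' Convolves all excitation lines (energy, oscillator strength) with a
#' Gaussian of given FWHM and decomposes the intensity into bins of the
#' chosen CT-class fraction (CS by default, or combined MLCT+IL).  Each
#' line is assigned to exactly one bin, so the bins sum to the total
#' spectrum exactly.
#'
#' @param records excitation records (from
#'   \code{\link{vertical_excitation_batch}}); rows with zero oscillator
#'   strength contribute nothing.
#' @param fwhm Gaussian full width at half maximum (eV).
#' @param grid energies at which to evaluate the spectrum (eV).
#' @param ct_mode \code{"CS"} bins by the CS fraction, \code{"MLCT+IL"}
#'   by the summed MLCT and IL fractions, \code{"none"} for no
#'   decomposition.
#' @param ct_breaks bin boundaries on the fraction in [0, 1].
#' @return data.frame with \code{energy}, \code{total} and one column per
#'   bin; Gaussian lineshapes are area-normalized so the energy integral
#'   of a single line equals its oscillator strength.
#' @export
compute_spectrum <- function(records, fwhm = 0.2,
                             grid = seq(2.0, 5.0, by = 0.01),
                             ct_mode = c("CS", "MLCT+IL", "none"),
                             ct_breaks = seq(0, 1, by = 0.25)) {
  ct_mode <- match.arg(ct_mode)
  if (nrow(records) == 0L) stop("no excitation records")
  lines <- records[records$f_osc > 0, , drop = FALSE]
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  out <- data.frame(energy = grid, total = 0)
  if (nrow(lines) == 0L) {
    warning("no lines with nonzero oscillator strength; zero spectrum")
    return(out)
  }
  gauss <- function(e0) exp(-(grid - e0)^2 / (2 * sigma^2)) /
    (sigma * sqrt(2 * pi))
  frac <- switch(ct_mode,
                 "CS" = lines$frac_CS,
                 "MLCT+IL" = lines$frac_MLCT + lines$frac_IL,
                 "none" = NULL)
  if (ct_mode != "none" && is.null(frac))
    stop("records carry no CT fractions; use ct_mode = 'none'")
  if (ct_mode == "none") {
    for (k in seq_len(nrow(lines)))
      out$total <- out$total + lines$f_osc[k] * gauss(lines$energy[k])
    return(out)
  }
  nb <- length(ct_breaks) - 1L
  bins <- matrix(0, length(grid), nb)
  bin_of <- pmin(pmax(findInterval(frac, ct_breaks, rightmost.closed = TRUE),
                      1L), nb)
  for (k in seq_len(nrow(lines))) {
    g <- lines$f_osc[k] * gauss(lines$energy[k])
    bins[, bin_of[k]] <- bins[, bin_of[k]] + g
  }
  colnames(bins) <- sprintf("bin_%g_%g", utils::head(ct_breaks, -1L),
                            utils::tail(ct_breaks, -1L))
  out$total <- rowSums(bins)
  cbind(out, as.data.frame(bins))
}

#' Stochastic selection of initial electronic states
#'
#' Selects initial (geometry, MCH state) pairs inside an excitation
#' energy window based on oscillator strengths.  In the default
#' \code{"rejection"} mode each eligible pair is accepted independently
#' with probability \eqn{f / f_{max}} over the eligible set (global
#' maximum); \code{"fixed"} mode draws exactly \code{n_select} pairs with
#' probability proportional to \eqn{f} (with replacement across
#' geometries, without duplicating a pair).
#'
#' @param records excitation records with \code{sample_id}.
#' @param window c(lo, hi) excitation window (eV).
#' @param seed integer seed.
#' @param mode \code{"rejection"} or \code{"fixed"}.
#' @param n_select number of selections for \code{"fixed"} mode.
#' @return data.frame with \code{sample_id}, \code{state} (spin-free MCH
#'   index), \code{label}, \code{energy}, \code{f_osc}; per-state tallies
#'   in \code{attr(, "tally")}.
#' @export
select_initial_states <- function(records, window = c(2.8, 3.2), seed = 1L,
                                  mode = c("rejection", "fixed"),
                                  n_select = NULL) {
  mode <- match.arg(mode)
  if (window[1] > window[2]) stop("window must be ordered")
  elig <- records[records$energy >= window[1] &
                  records$energy <= window[2] &
                  records$f_osc > 0, , drop = FALSE]
  if (nrow(elig) == 0L) {
    warning("no eligible states in the excitation window")
    sel <- records[0, , drop = FALSE]
  } else {
    set.seed(as.integer(seed))
    if (mode == "rejection") {
      fmax <- max(elig$f_osc)
      keep <- stats::runif(nrow(elig)) < elig$f_osc / fmax
      sel <- elig[keep, , drop = FALSE]
    } else {
      if (is.null(n_select)) stop("fixed mode requires n_select")
      idx <- sample.int(nrow(elig), size = n_select, replace = TRUE,
                        prob = elig$f_osc)
      sel <- elig[unique(idx), , drop = FALSE]
      if (nrow(sel) < n_select) {
        ## top up without duplicating pairs
        remaining <- setdiff(seq_len(nrow(elig)), unique(idx))
        extra <- utils::head(remaining[order(-elig$f_osc[remaining])],
                             n_select - nrow(sel))
        sel <- elig[sort(c(unique(idx), extra)), , drop = FALSE]
      }
    }
  }
  sel <- sel[, intersect(c("sample_id", "state", "label", "energy", "f_osc"),
                         colnames(sel)), drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "tally") <- table(sel$label)
  attr(sel, "window") <- window
  sel
}
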