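#' Load the packaged vertical-excitation fixture
#'
#' Reads the packaged table of TDA-B3LYP vertical excitation energies,
#' oscillator strengths and fragment charge-transfer percentages of the
#' 19 excited singlet and 17 triplet diabatic basis states of the
#' Trp-[Re(CO)3(Dmp)(His)]+ chromophore, and assembles an LVC parameter
#' skeleton: a 20-singlet/17-triplet electronic basis with vertical shifts
#' \eqn{\epsilon_n} from the energy column and a diagonal CT-number table
#' from the percentage columns.  \eqn{\kappa}, \eqn{\lambda}, SOC and
#' dipoles are left at zero for the user or the synthetic generator to
#' fill.  The closed-shell ground state carries a unit rest-fragment
#' placeholder weight in the CT table (it is no excitation).
#'
#' @return list with elements \code{basis} (\code{electronic_basis}),
#'   \code{parameters} (\code{lvc_parameters} skeleton, one dummy mode),
#'   \code{ct_table} (\code{ct_number_table}), \code{f_osc} (named vector,
#'   excited singlets), \code{characters} (printed character labels) and
#'   \code{table} (the raw data.frame).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_vertical_excitations.tsv",
                      package = "lvcdyn", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 36L)
  ns_exc <- sum(tab$mult == 1L)
  nt <- sum(tab$mult == 3L)
  basis <- electronic_basis(ns_exc + 1L, nt,
                            labels = c("S0", tab$state))
  epsilon <- c(0, tab$E_eV)

  fragments <- c("Trp", "His", "Dmp", "ReCO3", "Rest")
  n_sf <- basis$n_sf
  om <- array(0, c(n_sf, n_sf, 5L, 5L))
  om[1L, 1L, 5L, 5L] <- 1  # ground-state placeholder (no excitation)
  pair_cols <- list(
    ct_Trp_Trp = c(1L, 1L), ct_Trp_Dmp = c(1L, 3L),
    ct_Trp_ReCO3 = c(1L, 4L), ct_His_Dmp = c(2L, 3L),
    ct_Dmp_Dmp = c(3L, 3L), ct_ReCO3_Dmp = c(4L, 3L),
    ct_ReCO3_ReCO3 = c(4L, 4L), ct_others = c(5L, 5L))
  for (r in seq_len(nrow(tab))) {
    n <- r + 1L  # state index in the basis (after S0)
    for (cc in names(pair_cols)) {
      ij <- pair_cols[[cc]]
      om[n, n, ij[1], ij[2]] <- tab[[cc]][r] / 100
    }
    ## printed percentages are rounded and may total 101; renormalize the
    ## rare excess so the (0, 1] weight invariant holds
    tot <- sum(om[n, n, , ])
    if (tot > 1) om[n, n, , ] <- om[n, n, , ] / tot
  }
  ct <- ct_number_table(fragments, om, basis$labels)

  params <- lvc_parameters(basis, epsilon, n_modes = 1L)
  f_osc <- tab$f_osc[tab$mult == 1L]
  names(f_osc) <- tab$state[tab$mult == 1L]
  characters <- tab$character
  names(characters) <- tab$state
  list(basis = basis, parameters = params, ct_table = ct,
       f_osc = f_osc, characters = characters, table = tab)
}
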