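## Physical constants (CODATA 2018) and unit conversions.
## Internal convention: atomic units (hbar = 1); user interfaces use
## eV (energies), fs (times), Angstrom (lengths), amu (masses),
## cm^-1 (frequencies); normal-mode coordinates Q are dimensionless
## (mass-frequency scaled).

#' Unit conversion constants
#'
#' Named list of conversion factors between the package's interface units
#' (eV, fs, Angstrom, amu, cm^-1) and internal atomic units.
#'
#' @format list with elements \code{ev_per_hartree}, \code{hartree_per_ev},
#'   \code{ev_per_cm1}, \code{bohr_per_angstrom}, \code{me_per_amu},
#'   \code{au_per_fs}, \code{nm_ev} (product lambda[nm] * E[eV]).
#' @export
lvc_units <- list(
  ev_per_hartree   = 27.211386245988,
  hartree_per_ev   = 1 / 27.211386245988,
  ev_per_cm1       = 1 / 8065.543937349212,
  bohr_per_angstrom = 1.8897261246257702,
  me_per_amu       = 1822.888486209,
  au_per_fs        = 41.341373335182114,
  nm_ev            = 1239.84198433,
  hbar_ev_fs       = 0.6582119569509066
)

ev2au <- function(x) x * lvc_units$hartree_per_ev
au2ev <- function(x) x * lvc_units$ev_per_hartree
cm12ev <- function(x) x * lvc_units$ev_per_cm1
fs2au <- function(x) x * lvc_units$au_per_fs
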