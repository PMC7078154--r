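#' Electronic basis bookkeeping
#'
#' Defines the spin-free diabatic state list (singlets first, including the
#' ground state, then triplets) and its spin expansion.  The spin-expanded
#' basis of dimension \eqn{D = n_s + 3 n_t} orders the singlets first and
#' then replicates each triplet for \eqn{M_S \in \{-1, 0, +1\}}, grouped by
#' \eqn{M_S} block, which is the layout expected for the spin-orbit matrix.
#'
#' @param n_singlets number of singlet states including the ground state.
#' @param n_triplets number of triplet states.
#' @param labels optional character vector of unique state labels, length
#'   \code{n_singlets + n_triplets}; defaults to S0..S(n-1), T1..Tn.
#' @return object of class \code{electronic_basis}.
#' @export
electronic_basis <- function(n_singlets, n_triplets, labels = NULL) {
  n_singlets <- as.integer(n_singlets)
  n_triplets <- as.integer(n_triplets)
  if (n_singlets < 1L) stop("need at least the singlet ground state")
  if (n_triplets < 0L) stop("n_triplets must be >= 0")
  n_sf <- n_singlets + n_triplets
  if (is.null(labels)) {
    labels <- c(paste0("S", seq_len(n_singlets) - 1L),
                if (n_triplets > 0L) paste0("T", seq_len(n_triplets)))
  }
  if (length(labels) != n_sf || anyDuplicated(labels))
    stop("labels must be unique and cover all spin-free states")
  structure(
    list(n_singlets = n_singlets, n_triplets = n_triplets,
         n_sf = n_sf, dim = n_singlets + 3L * n_triplets,
         labels = labels,
         multiplicity = rep(c(1L, 3L), c(n_singlets, n_triplets))),
    class = "electronic_basis")
}

#' @export
print.electronic_basis <- function(x, ...) {
  cat(sprintf("<electronic_basis> %d singlets + %d triplets (D = %d)\n",
              x$n_singlets, x$n_triplets, x$dim))
  invisible(x)
}

## Map spin-expanded index -> spin-free state index.
## Order: S_1..S_ns, then T block at MS=-1, MS=0, MS=+1.
spin_expansion_map <- function(basis) {
  ns <- basis$n_singlets; nt <- basis$n_triplets
  c(seq_len(ns), rep(ns + seq_len(nt), times = 3L))
}

## MS quantum number per spin-expanded index (0 for singlets).
spin_expansion_ms <- function(basis) {
  ns <- basis$n_singlets; nt <- basis$n_triplets
  c(rep(0L, ns), rep(c(-1L, 0L, 1L), each = nt))
}

## Expand a spin-free (n_sf x n_sf) matrix to the spin basis (D x D),
## zero between different multiplicities / different MS blocks.
spin_expand_matrix <- function(basis, A) {
  map <- spin_expansion_map(basis)
  ms <- spin_expansion_ms(basis)
  mult <- basis$multiplicity[map]
  B <- A[map, map, drop = FALSE]
  same <- outer(ms, ms, "==") & outer(mult, mult, "==")
  B[!same] <- 0
  B
}

## Labels of the spin-expanded basis.
spin_expansion_labels <- function(basis) {
  map <- spin_expansion_map(basis)
  ms <- spin_expansion_ms(basis)
  lab <- basis$labels[map]
  ifelse(basis$multiplicity[map] == 3L,
         sprintf("%s(ms=%+d)", lab, ms), lab)
}
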