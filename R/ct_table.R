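#' Fragment charge-transfer number table
#'
#' Stores the fragment-pair charge-transfer weights
#' \eqn{\Omega_{AB}^{(n,m)}} of the diabatic states: for \eqn{n = m} the
#' usual CT numbers of state n (hole on fragment A, electron on fragment
#' B), for \eqn{n \ne m} the "transition" CT numbers of a state pair.
#' Weights are dimensionless; for each state the diagonal table sums to a
#' value in (0, 1] (weights not resolved into the named fragments may be
#' carried by a rest fragment).
#'
#' @param fragments character vector of ordered fragment labels.
#' @param omega numeric array (n_states x n_states x n_frag x n_frag),
#'   symmetric in the two state indices.
#' @param state_labels optional labels of the diabatic states.
#' @return object of class \code{ct_number_table}.
#' @export
ct_number_table <- function(fragments, omega, state_labels = NULL) {
  fragments <- as.character(fragments)
  nfr <- length(fragments)
  if (anyDuplicated(fragments)) stop("fragment labels must be unique")
  d <- dim(omega)
  if (length(d) != 4L || d[1] != d[2] || d[3] != nfr || d[4] != nfr)
    stop("omega must be n_states x n_states x n_frag x n_frag")
  n_states <- d[1]
  sym <- max(abs(omega - aperm(omega, c(2L, 1L, 3L, 4L))))
  if (sym > 1e-10) stop("omega must be symmetric in the state indices")
  tot <- vapply(seq_len(n_states), function(n) sum(omega[n, n, , ]),
                numeric(1))
  if (any(tot <= 0) || any(tot > 1 + 1e-8))
    stop("diagonal CT weights of each state must sum into (0, 1]")
  if (is.null(state_labels)) state_labels <- paste0("state", seq_len(n_states))
  structure(list(fragments = fragments, omega = omega,
                 n_states = n_states, state_labels = state_labels),
            class = "ct_number_table")
}

#' @export
print.ct_number_table <- function(x, ...) {
  cat(sprintf("<ct_number_table> %d states, fragments: %s\n",
              x$n_states, paste(x$fragments, collapse = ", ")))
  invisible(x)
}

subset_ct_table <- function(ct, keep_states) {
  ct_number_table(ct$fragments,
                  ct$omega[keep_states, keep_states, , , drop = FALSE],
                  ct$state_labels[keep_states])
}

## The seven hole->electron fragment-pair character classes of the
## Re(CO)3(Dmp)(His)/Trp chromophore, plus the catch-all "Others".
## Precedence resolves exact ties deterministically.
ct_class_definitions <- function() {
  data.frame(
    hole = c("Trp", "ReCO3", "His", "Dmp", "Trp", "Trp", "ReCO3"),
    elec = c("Dmp", "Dmp", "Dmp", "Dmp", "Trp", "ReCO3", "ReCO3"),
    class = c("CS", "MLCT", "LLCT", "IL", "AC", "AMCS", "MC"),
    stringsAsFactors = FALSE)
}

#' Classify the character of a CT-number row
#'
#' Assigns one of the seven fragment-pair character classes (CS, MLCT,
#' LLCT, IL, AC, AMCS, MC) from the largest fragment-pair weight of a
#' state: Trp to Dmp is charge-separated (CS), Re(CO)3 to Dmp is MLCT,
#' His to Dmp is LLCT, Dmp-local is intraligand (IL), Trp-local is amino
#' acid centred (AC), Trp to Re(CO)3 is AMCS and Re(CO)3-local is metal
#' centred (MC); any other dominant pair (including a rest fragment)
#' returns "Others".  Exact ties are broken by the declared precedence
#' CS > MLCT > LLCT > IL > AC > AMCS > MC.
#'
#' @param ct_row square matrix of fragment-pair weights (hole in rows,
#'   electron in columns), with \code{dimnames} or paired with
#'   \code{fragments}.
#' @param fragments fragment labels matching the row/column order.
#' @return character class label.
#' @export
classify_character <- function(ct_row, fragments = rownames(ct_row)) {
  ct_row <- as.matrix(ct_row)
  if (is.null(fragments)) stop("fragment labels required")
  if (all(ct_row == 0)) return("Others")
  defs <- ct_class_definitions()
  best <- "Others"; best_w <- -Inf
  for (k in seq_len(nrow(defs))) {
    i <- match(defs$hole[k], fragments)
    j <- match(defs$elec[k], fragments)
    if (is.na(i) || is.na(j)) next
    w <- ct_row[i, j]
    if (w > best_w + 1e-12) { best_w <- w; best <- defs$class[k] }
  }
  ## a dominant unlisted pair outweighs every named class
  named <- matrix(FALSE, nrow(ct_row), ncol(ct_row))
  for (k in seq_len(nrow(defs))) {
    i <- match(defs$hole[k], fragments)
    j <- match(defs$elec[k], fragments)
    if (!is.na(i) && !is.na(j)) named[i, j] <- TRUE
  }
  if (any(ct_row[!named] > best_w + 1e-12)) return("Others")
  best
}

## Expand the spin-free CT array for fragment pair (A,B) to the
## spin-expanded basis (block-diagonal in MS and multiplicity).
ct_pair_matrix_expanded <- function(basis, ct, a, b) {
  spin_expand_matrix(basis, ct$omega[, , a, b])
}

#' Charge-transfer numbers of an electronic wavefunction
#'
#' Evaluates \eqn{\Omega^{el}_{AB} = \sum_{n,m} c^*_n c_m
#' \Omega^{(n,m)}_{AB}} for a coefficient vector in the (spin-expanded)
#' diabatic basis.  Cross terms are restricted to states of equal
#' multiplicity and MS (others carry no transition CT numbers).
#'
#' @param c_diab complex coefficient vector, length D (spin-expanded) or
#'   n_sf (spin-free).
#' @param ct a \code{ct_number_table}.
#' @param basis the \code{electronic_basis}.
#' @return matrix n_frag x n_frag of real CT weights (imaginary residue
#'   checked to be < 1e-8).
#' @export
wavefunction_ct_numbers <- function(c_diab, ct, basis) {
  nfr <- length(ct$fragments)
  out <- matrix(0, nfr, nfr,
                dimnames = list(ct$fragments, ct$fragments))
  if (length(c_diab) == basis$n_sf) {
    map <- seq_len(basis$n_sf)
    cx <- as.complex(c_diab)
    for (a in seq_len(nfr)) for (b in seq_len(nfr)) {
      v <- Conj(cx) %*% ct$omega[, , a, b] %*% cx
      out[a, b] <- check_real(v)
    }
  } else if (length(c_diab) == basis$dim) {
    cx <- as.complex(c_diab)
    for (a in seq_len(nfr)) for (b in seq_len(nfr)) {
      M <- ct_pair_matrix_expanded(basis, ct, a, b)
      v <- Conj(cx) %*% M %*% cx
      out[a, b] <- check_real(v)
    }
  } else stop("coefficient vector has wrong length")
  out
}

check_real <- function(v, tol = 1e-8) {
  v <- as.complex(v)
  if (abs(Im(v)) > tol)
    stop(sprintf("imaginary residue %.3g exceeds tolerance", Im(v)))
  Re(v)
}
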