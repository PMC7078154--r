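## Plain-text LVC parameter file format (schema "LVC-MODEL v1").
##
## Key-block layout, tolerant of '#' comments and blank lines on reading;
## the writer emits a canonical sorted order with 17-significant-digit
## numbers so files diff cleanly and numeric values round-trip losslessly.
##
##   LVC-MODEL v1
##   units energy=eV length=Angstrom mass=amu frequency=cm-1
##   nsinglets / ntriplets / natoms / nmodes  <int>
##   labels <tok> ...
##   geometry        natoms lines: mass x y z
##   frequencies     one value per line
##   kmatrix         3*natoms lines with nmodes values
##   epsilon         lines: mult idx value        (idx within multiplicity)
##   kappa           lines: mult idx mode value   (nonzero records only)
##   lambda          lines: mult idx1 idx2 mode value (idx1 < idx2)
##   soc_real / soc_imag   D lines with D values
##   dm_x / dm_y / dm_z    n_sf lines
##   ct_fragments <tok> ...
##   ct_diagonal     lines: state fragA fragB value   (spin-free index)
##   ct_transition   lines: state1 state2 fragA fragB value (state1 < state2)
##   end

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an LVC model to a text file
#'
#' Serializes reference, parameters and (if present) the CT-number table in
#' the canonical key-block text format; see the package vignette for the
#' schema.  Records are emitted in sorted order so re-serialization of a
#' read model reproduces the file byte for byte.
#'
#' @param model an \code{lvc_model}.
#' @param path output file path.
#' @return invisibly \code{path}.
#' @export
write_lvc_model <- function(model, path) {
  p <- model$parameters; ref <- model$reference; basis <- p$basis
  mult_idx <- function(i) {
    m <- basis$multiplicity[i]
    k <- if (m == 1L) i else i - basis$n_singlets
    c(m, k)
  }
  out <- c("LVC-MODEL v1",
           "units energy=eV length=Angstrom mass=amu frequency=cm-1",
           paste("nsinglets", basis$n_singlets),
           paste("ntriplets", basis$n_triplets),
           paste("natoms", ref$n_atoms),
           paste("nmodes", ref$n_modes),
           paste(c("labels", basis$labels), collapse = " "),
           "geometry")
  for (a in seq_len(ref$n_atoms))
    out <- c(out, paste(fmt_num(c(ref$masses[a], ref$coords[a, ])),
                        collapse = " "))
  out <- c(out, "frequencies", fmt_num(ref$omega), "kmatrix")
  for (r in seq_len(nrow(ref$K)))
    out <- c(out, paste(fmt_num(ref$K[r, ]), collapse = " "))
  out <- c(out, "epsilon")
  for (i in seq_len(basis$n_sf)) {
    mi <- mult_idx(i)
    out <- c(out, paste(mi[1], mi[2], fmt_num(p$epsilon[i])))
  }
  out <- c(out, "kappa")
  for (i in seq_len(basis$n_sf)) for (k in seq_len(p$n_modes)) {
    if (p$kappa[i, k] != 0) {
      mi <- mult_idx(i)
      out <- c(out, paste(mi[1], mi[2], k, fmt_num(p$kappa[i, k])))
    }
  }
  out <- c(out, "lambda")
  for (i in seq_len(basis$n_sf)) for (j in seq_len(basis$n_sf)) {
    if (j <= i) next
    for (k in seq_len(p$n_modes)) {
      if (p$lam[i, j, k] != 0) {
        mi <- mult_idx(i); mj <- mult_idx(j)
        out <- c(out, paste(mi[1], mi[2], mj[2], k,
                            fmt_num(p$lam[i, j, k])))
      }
    }
  }
  if (any(p$soc != 0)) {
    out <- c(out, "soc_real")
    for (r in seq_len(nrow(p$soc)))
      out <- c(out, paste(fmt_num(Re(p$soc[r, ])), collapse = " "))
    out <- c(out, "soc_imag")
    for (r in seq_len(nrow(p$soc)))
      out <- c(out, paste(fmt_num(Im(p$soc[r, ])), collapse = " "))
  }
  if (any(vapply(p$dipoles, function(m) any(m != 0), logical(1)))) {
    for (cc in c("x", "y", "z")) {
      out <- c(out, paste0("dm_", cc))
      m <- p$dipoles[[cc]]
      for (r in seq_len(nrow(m)))
        out <- c(out, paste(fmt_num(m[r, ]), collapse = " "))
    }
  }
  ct <- model$ct_table
  if (!is.null(ct)) {
    out <- c(out, paste(c("ct_fragments", ct$fragments), collapse = " "))
    nfr <- length(ct$fragments)
    out <- c(out, "ct_diagonal")
    for (n in seq_len(ct$n_states)) for (a in seq_len(nfr))
      for (b in seq_len(nfr))
        if (ct$omega[n, n, a, b] != 0)
          out <- c(out, paste(n, a, b, fmt_num(ct$omega[n, n, a, b])))
    out <- c(out, "ct_transition")
    for (n in seq_len(ct$n_states)) for (m2 in seq_len(ct$n_states)) {
      if (m2 <= n) next
      for (a in seq_len(nfr)) for (b in seq_len(nfr))
        if (ct$omega[n, m2, a, b] != 0)
          out <- c(out, paste(n, m2, a, b, fmt_num(ct$omega[n, m2, a, b])))
    }
  }
  out <- c(out, "end")
  writeLines(out, path)
  invisible(path)
}

#' Read an LVC model from a text file
#'
#' Parses the key-block text format written by \code{\link{write_lvc_model}}.
#' Comment lines (\code{#}) and blank lines are ignored.  A missing SOC
#' block yields a zero SOC matrix with a warning; missing dipole or CT
#' blocks yield zero dipoles / no CT table.  Malformed content raises an
#' error naming the offending line number and block.
#'
#' @param path input file path.
#' @return an \code{lvc_model}.
#' @export
read_lvc_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  txt <- sub("#.*$", "", raw)
  keep <- grepl("\\S", txt)
  txt <- trimws(txt[keep]); lineno <- lineno[keep]
  n <- length(txt)
  if (n == 0L || txt[1] != "LVC-MODEL v1")
    stop("line 1: missing 'LVC-MODEL v1' header")
  pos <- 2L
  bail <- function(block, msg)
    stop(sprintf("line %d (block %s): %s",
                 if (pos <= n) lineno[pos] else lineno[n], block, msg))
  take_kv <- function(key) {
    if (pos > n || !startsWith(txt[pos], key))
      bail(key, paste("expected", key))
    val <- sub(paste0("^", key, "\\s+"), "", txt[pos])
    pos <<- pos + 1L
    val
  }
  nums <- function(s) suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
  read_matrix <- function(nrow_, ncol_, block) {
    M <- matrix(0, nrow_, ncol_)
    for (r in seq_len(nrow_)) {
      if (pos > n) bail(block, "unexpected end of file")
      v <- nums(txt[pos])
      if (length(v) != ncol_ || anyNA(v))
        bail(block, sprintf("expected %d numeric values", ncol_))
      M[r, ] <- v
      pos <<- pos + 1L
    }
    M
  }

  take_kv("units")
  ns <- as.integer(take_kv("nsinglets"))
  nt <- as.integer(take_kv("ntriplets"))
  natoms <- as.integer(take_kv("natoms"))
  nmodes <- as.integer(take_kv("nmodes"))
  labels <- strsplit(take_kv("labels"), "\\s+")[[1]]
  basis <- electronic_basis(ns, nt, labels)
  n_sf <- basis$n_sf; D <- basis$dim

  if (pos > n || txt[pos] != "geometry") bail("geometry", "expected 'geometry'")
  pos <- pos + 1L
  geo <- read_matrix(natoms, 4L, "geometry")
  if (pos > n || txt[pos] != "frequencies")
    bail("frequencies", "expected 'frequencies'")
  pos <- pos + 1L
  omega <- as.numeric(read_matrix(nmodes, 1L, "frequencies"))
  if (pos > n || txt[pos] != "kmatrix") bail("kmatrix", "expected 'kmatrix'")
  pos <- pos + 1L
  K <- read_matrix(3L * natoms, nmodes, "kmatrix")
  reference <- harmonic_reference(geo[, 2:4, drop = FALSE], geo[, 1],
                                  omega, K)

  sf_index <- function(mult, idx, block) {
    if (mult == 1) {
      if (idx < 1 || idx > ns) bail(block, "singlet index out of range")
      idx
    } else if (mult == 3) {
      if (idx < 1 || idx > nt) bail(block, "triplet index out of range")
      ns + idx
    } else bail(block, "multiplicity must be 1 or 3")
  }

  epsilon <- numeric(n_sf)
  if (pos > n || txt[pos] != "epsilon") bail("epsilon", "expected 'epsilon'")
  pos <- pos + 1L
  for (i in seq_len(n_sf)) {
    v <- nums(txt[pos])
    if (length(v) != 3L || anyNA(v)) bail("epsilon", "expected 'mult idx value'")
    epsilon[sf_index(v[1], v[2], "epsilon")] <- v[3]
    pos <- pos + 1L
  }

  block_lines <- function(block) {
    recs <- list()
    while (pos <= n && grepl("^[-0-9]", txt[pos])) {
      v <- nums(txt[pos])
      if (anyNA(v)) bail(block, "non-numeric record")
      recs[[length(recs) + 1L]] <- v
      pos <<- pos + 1L
    }
    recs
  }

  kappa <- matrix(0, n_sf, nmodes)
  lam <- array(0, c(n_sf, n_sf, nmodes))
  if (pos <= n && txt[pos] == "kappa") {
    pos <- pos + 1L
    for (v in block_lines("kappa")) {
      if (length(v) != 4L) bail("kappa", "expected 'mult idx mode value'")
      i <- sf_index(v[1], v[2], "kappa")
      if (v[3] < 1 || v[3] > nmodes) bail("kappa", "mode index out of range")
      kappa[i, v[3]] <- v[4]
    }
  }
  if (pos <= n && txt[pos] == "lambda") {
    pos <- pos + 1L
    for (v in block_lines("lambda")) {
      if (length(v) != 5L) bail("lambda", "expected 'mult idx1 idx2 mode value'")
      i <- sf_index(v[1], v[2], "lambda")
      j <- sf_index(v[1], v[3], "lambda")
      if (v[4] < 1 || v[4] > nmodes) bail("lambda", "mode index out of range")
      lam[i, j, v[4]] <- v[5]
      lam[j, i, v[4]] <- v[5]
    }
  }

  soc <- matrix(0 + 0i, D, D)
  if (pos <= n && txt[pos] == "soc_real") {
    pos <- pos + 1L
    re <- read_matrix(D, D, "soc_real")
    im <- matrix(0, D, D)
    if (pos <= n && txt[pos] == "soc_imag") {
      pos <- pos + 1L
      im <- read_matrix(D, D, "soc_imag")
    }
    soc <- re + 1i * im
  } else {
    warning("model file has no SOC block; using zero spin-orbit couplings")
  }

  dipoles <- list(x = matrix(0, n_sf, n_sf), y = matrix(0, n_sf, n_sf),
                  z = matrix(0, n_sf, n_sf))
  for (cc in c("x", "y", "z")) {
    key <- paste0("dm_", cc)
    if (pos <= n && txt[pos] == key) {
      pos <- pos + 1L
      dipoles[[cc]] <- read_matrix(n_sf, n_sf, key)
    }
  }

  ct <- NULL
  if (pos <= n && startsWith(txt[pos], "ct_fragments")) {
    fragments <- strsplit(take_kv("ct_fragments"), "\\s+")[[1]]
    nfr <- length(fragments)
    om <- array(0, c(n_sf, n_sf, nfr, nfr))
    if (pos <= n && txt[pos] == "ct_diagonal") {
      pos <- pos + 1L
      for (v in block_lines("ct_diagonal")) {
        if (length(v) != 4L) bail("ct_diagonal", "expected 'state a b value'")
        om[v[1], v[1], v[2], v[3]] <- v[4]
      }
    }
    if (pos <= n && txt[pos] == "ct_transition") {
      pos <- pos + 1L
      for (v in block_lines("ct_transition")) {
        if (length(v) != 5L)
          bail("ct_transition", "expected 'state1 state2 a b value'")
        om[v[1], v[2], v[3], v[4]] <- v[5]
        om[v[2], v[1], v[3], v[4]] <- v[5]
      }
    }
    ct <- ct_number_table(fragments, om, basis$labels)
  }
  if (pos > n || txt[pos] != "end") bail("end", "expected 'end'")

  params <- lvc_parameters(basis, epsilon, kappa, lam, soc, dipoles,
                           n_modes = nmodes)
  lvc_model(reference, params, ct)
}
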