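## Text ensemble archive (schema v1): a directory with manifest.json and
## one wide TSV per trajectory.  Complex arrays are stored as paired
## real/imaginary columns; numbers are written with 17 significant digits
## so all values round-trip losslessly.  The format is deliberately plain
## text so no binary dependency is ever needed to read an archive.

archive_schema_version <- 1L

traj_to_frame <- function(traj) {
  nf <- ncol(traj$Q)
  n_sf <- ncol(traj$E_mch)
  D <- ncol(traj$E_diag)
  n <- length(traj$times)
  df <- data.frame(time = traj$times, active = traj$active,
                   ekin = traj$ekin, etot = traj$etot)
  add <- function(prefix, M) {
    M <- as.matrix(M)
    colnames(M) <- paste0(prefix, seq_len(ncol(M)))
    cbind(df, M)
  }
  df <- add("Q", traj$Q)
  df <- add("P", traj$P)
  df <- add("Emch", traj$E_mch)
  df <- add("Ediag", traj$E_diag)
  df <- add("cRe", Re(traj$c_diag))
  df <- add("cIm", Im(traj$c_diag))
  usf <- t(vapply(seq_len(n), function(k) as.numeric(traj$U_sf[, , k]),
                  numeric(n_sf * n_sf)))
  colnames(usf) <- paste0("Usf", seq_len(n_sf * n_sf))
  ud <- t(vapply(seq_len(n), function(k) c(Re(traj$U_diag[, , k]),
                                           Im(traj$U_diag[, , k])),
                 numeric(2L * D * D)))
  colnames(ud) <- c(paste0("UdRe", seq_len(D * D)),
                    paste0("UdIm", seq_len(D * D)))
  cbind(df, usf, ud)
}

frame_to_traj <- function(df, basis, nf, settings) {
  n_sf <- basis$n_sf
  D <- basis$dim
  n <- nrow(df)
  grab <- function(prefix, k) as.matrix(df[paste0(prefix, seq_len(k))])
  U_sf <- array(t(grab("Usf", n_sf * n_sf)), c(n_sf, n_sf, n))
  U_diag <- array(complex(real = t(grab("UdRe", D * D)),
                          imaginary = t(grab("UdIm", D * D))),
                  c(D, D, n))
  structure(
    list(times = df$time, Q = unname(grab("Q", nf)),
         P = unname(grab("P", nf)), active = df$active,
         E_mch = unname(grab("Emch", n_sf)),
         E_diag = unname(grab("Ediag", D)),
         c_diag = unname(matrix(complex(real = grab("cRe", D),
                                        imaginary = grab("cIm", D)),
                                n, D)),
         U_sf = U_sf, U_diag = U_diag,
         ekin = df$ekin, etot = df$etot,
         hops = NULL, energy_drift = NA_real_, valid = TRUE,
         basis = basis, n_modes = nf, settings = settings),
    class = "lvc_trajectory")
}

#' Archive an ensemble to a directory of text files
#'
#' Writes \code{manifest.json} (schema version, counts, seed, settings)
#' and one TSV per trajectory with all per-step data (coordinates,
#' momenta, energies, complex coefficients and transforms as paired
#' real/imaginary columns).  Storage is lossless: numbers carry 17
#' significant digits.
#'
#' @param ensemble an \code{lvc_ensemble}.
#' @param dir output directory (created if needed).
#' @return invisibly \code{dir}.
#' @export
archive_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  basis <- ensemble$basis
  trajs <- ensemble$trajectories
  manifest <- list(
    schema_version = archive_schema_version,
    n_trajectories = length(trajs),
    n_singlets = basis$n_singlets, n_triplets = basis$n_triplets,
    n_modes = ensemble$n_modes,
    seed = ensemble$seed,
    settings = unclass(ensemble$settings),
    failed = which(vapply(trajs, is.null, logical(1))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(trajs)) {
    if (is.null(trajs[[k]])) next
    df <- traj_to_frame(trajs[[k]])
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.table(df, file.path(dir, sprintf("traj_%04d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load an archived ensemble
#'
#' Reads an archive written by \code{\link{archive_ensemble}}.  A schema
#' version other than the supported one raises an explicit version
#' error; a corrupt trajectory file raises an error naming the
#' trajectory index.
#'
#' @param dir archive directory.
#' @return an \code{lvc_ensemble}.
#' @export
load_ensemble <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version),
                 archive_schema_version))
    stop(sprintf("unsupported archive schema version %s (supported: %d)",
                 manifest$schema_version, archive_schema_version))
  basis <- electronic_basis(manifest$n_singlets, manifest$n_triplets)
  nf <- manifest$n_modes
  settings <- manifest$settings
  n <- manifest$n_trajectories
  trajs <- vector("list", n)
  expected_cols <- NULL
  expected_rows <- NULL
  for (k in seq_len(n)) {
    if (k %in% manifest$failed) next
    fp <- file.path(dir, sprintf("traj_%04d.tsv", k))
    traj <- tryCatch({
      df <- utils::read.delim(fp, check.names = FALSE)
      if (is.null(expected_cols)) expected_cols <- ncol(df)
      if (is.null(expected_rows)) expected_rows <- nrow(df)
      if (ncol(df) != expected_cols || nrow(df) != expected_rows ||
          anyNA(df))
        stop("incomplete data")
      frame_to_traj(df, basis, nf, settings)
    }, error = function(e)
      stop(sprintf("archive corrupt at trajectory %d: %s", k,
                   conditionMessage(e))))
    trajs[[k]] <- traj
  }
  structure(
    list(trajectories = trajs, failures = NULL, selections = NULL,
         settings = settings, basis = basis, n_modes = nf,
         seed = manifest$seed),
    class = "lvc_ensemble")
}

#' Hash of a model's canonical serialization
#'
#' MD5 of the canonical text serialization, used in run manifests to tie
#' outputs to their inputs.
#'
#' @param model an \code{lvc_model}.
#' @return character MD5 digest.
#' @export
model_hash <- function(model) {
  tf <- tempfile(fileext = ".lvc")
  on.exit(unlink(tf))
  write_lvc_model(model, tf)
  unname(tools::md5sum(tf))
}
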