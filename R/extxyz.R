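# Extended-XYZ reader/writer. Dialect: the comment line carries
# `Energy=<float>` when an energy label is present; per-atom lines are
# `symbol x y z [fx fy fz]` with forces in columns 5-7 when present.
# Coordinates in Angstrom, energies kcal/mol, forces kcal/mol/Angstrom.

#' Read a conformational dataset from an extended-XYZ file
#'
#' Every frame must have the same element sequence. Energies are parsed from
#' an `Energy=<float>` key on the comment line; forces from per-atom columns
#' 5-7 when present.
#'
#' @param path Path to the file.
#' @param name Dataset name; defaults to the file name.
#' @return A [mol_dataset()].
#' @export
read_extxyz <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  confs <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("parse error at line %d: expected atom count, got '%s'",
                   ln, lines[ln]))
    }
    if (ln + 1L + n > length(lines)) {
      stop(sprintf("parse error at line %d: frame truncated (expected %d atom rows)",
                   ln, n))
    }
    comment <- lines[ln + 1L]
    E <- NULL
    m <- regmatches(comment,
                    regexpr("Energy=([^[:space:]]+)", comment, perl = TRUE))
    if (length(m) == 1L && nzchar(m)) {
      E <- suppressWarnings(as.numeric(sub("Energy=", "", m)))
      if (is.na(E)) stop(sprintf("parse error at line %d: bad Energy value", ln + 1L))
    }
    sym <- character(n)
    R <- matrix(0, n, 3L)
    F <- matrix(0, n, 3L)
    has_forces <- TRUE
    for (k in seq_len(n)) {
      lno <- ln + 1L + k
      tok <- strsplit(trimws(lines[lno]), "[[:space:]]+")[[1L]]
      if (length(tok) < 4L) {
        stop(sprintf("parse error at line %d: expected 'symbol x y z [fx fy fz]'", lno))
      }
      sym[k] <- tok[1L]
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) stop(sprintf("parse error at line %d: bad coordinate", lno))
      R[k, ] <- xyz
      if (length(tok) >= 7L) {
        f <- suppressWarnings(as.numeric(tok[5:7]))
        if (anyNA(f)) stop(sprintf("parse error at line %d: bad force component", lno))
        F[k, ] <- f
      } else {
        has_forces <- FALSE
      }
    }
    z <- symbols_to_z(sym)
    confs[[length(confs) + 1L]] <-
      conformation(z, R, E = E, F = if (has_forces) F else NULL)
    ln <- ln + 2L + n
  }
  if (length(confs) == 0L) stop("parse error: no frames found in ", path)
  mol_dataset(confs, name = name)
}

#' Write a conformational dataset to an extended-XYZ file
#'
#' Floating point values are written with 15 significant digits so that a
#' read/write round trip reproduces coordinates, energies and forces to
#' better than 1e-10.
#'
#' @param dataset A [mol_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_extxyz <- function(dataset, path) {
  stopifnot(inherits(dataset, "mol_dataset"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot open '", path,
                                           "' for writing"))
  on.exit(close(con))
  fmt <- function(x) sprintf("%.15g", x)
  for (cf in dataset$conformations) {
    n <- length(cf$z)
    writeLines(as.character(n), con)
    comment <- if (!is.null(cf$E)) paste0("Energy=", fmt(cf$E)) else ""
    writeLines(comment, con)
    sym <- z_to_symbols(cf$z)
    for (k in seq_len(n)) {
      row <- c(sym[k], fmt(cf$R[k, ]))
      if (!is.null(cf$F)) row <- c(row, fmt(cf$F[k, ]))
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}

#' Save a dataset as a key-value archive
#'
#' Stores the dataset as a tagged list of arrays (`z`, `R` of shape
#' M x N x 3, `E` length M, `F` of shape M x N x 3) in RDS form, which is
#' much faster to reload than text XYZ for large trajectories.
#'
#' @param dataset A [mol_dataset()].
#' @param path Output path (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mol_dataset"))
  M <- length(dataset)
  z <- dataset_z(dataset)
  n <- length(z)
  Rarr <- array(0, c(M, n, 3L))
  has_E <- !is.null(dataset[[1L]]$E)
  has_F <- !is.null(dataset[[1L]]$F)
  Evec <- if (has_E) numeric(M) else NULL
  Farr <- if (has_F) array(0, c(M, n, 3L)) else NULL
  for (i in seq_len(M)) {
    cf <- dataset[[i]]
    Rarr[i, , ] <- cf$R
    if (has_E) Evec[i] <- cf$E
    if (has_F) Farr[i, , ] <- cf$F
  }
  saveRDS(list(format = "sgdml-dataset-1", name = dataset$name, z = z,
               R = Rarr, E = Evec, F = Farr), path)
  invisible(path)
}

#' Load a dataset saved by [save_dataset()]
#' @param path Path to the archive.
#' @return A [mol_dataset()].
#' @export
load_dataset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sgdml-dataset-1")) {
    stop("not an sgdml dataset archive: ", path)
  }
  M <- dim(obj$R)[1L]
  confs <- vector("list", M)
  for (i in seq_len(M)) {
    confs[[i]] <- conformation(obj$z, obj$R[i, , ],
                               E = if (!is.null(obj$E)) obj$E[i] else NULL,
                               F = if (!is.null(obj$F)) obj$F[i, , ] else NULL)
  }
  mol_dataset(confs, name = obj$name)
}
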