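# Core containers: a single molecular conformation and an ordered dataset of
# conformations sharing one atom composition/ordering. Units are fixed
# throughout the package: Angstrom for coordinates, kcal/mol for energies,
# kcal/mol/Angstrom for forces.

#' Create a molecular conformation
#'
#' @param z Integer vector of N nuclear charges.
#' @param R N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param E Optional scalar energy (kcal/mol).
#' @param F Optional N x 3 matrix of forces (kcal/mol/Angstrom).
#' @return An object of class `conformation`.
#' @export
conformation <- function(z, R, E = NULL, F = NULL) {
  z <- as.integer(z)
  R <- as.matrix(R)
  storage.mode(R) <- "double"
  n <- length(z)
  if (n < 2L) stop("a conformation needs at least 2 atoms")
  if (!all(dim(R) == c(n, 3L))) stop("R must be an N x 3 matrix matching z")
  if (!all(is.finite(R))) stop("coordinates must be finite")
  if (!is.null(E)) {
    E <- as.numeric(E)
    if (length(E) != 1L || !is.finite(E)) stop("E must be a finite scalar")
  }
  if (!is.null(F)) {
    F <- as.matrix(F)
    storage.mode(F) <- "double"
    if (!all(dim(F) == dim(R))) stop("F must have the same shape as R")
    if (!all(is.finite(F))) stop("forces must be finite")
  }
  structure(list(z = z, R = R, E = E, F = F), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation: %d atoms [%s]%s%s>\n",
              length(x$z), paste(z_to_symbols(x$z), collapse = ""),
              if (!is.null(x$E)) sprintf(", E = %.6g kcal/mol", x$E) else "",
              if (!is.null(x$F)) ", forces" else ""))
  invisible(x)
}

#' Create a conformational dataset
#'
#' An ordered, indexable collection of conformations with identical nuclear
#' charge vectors (same atom count and element ordering).
#'
#' @param conformations List of `conformation` objects.
#' @param name Dataset name.
#' @return An object of class `mol_dataset`.
#' @export
mol_dataset <- function(conformations, name = "dataset") {
  if (length(conformations) < 1L) stop("dataset must be non-empty")
  if (!all(vapply(conformations, inherits, logical(1), "conformation"))) {
    stop("all members must be conformation objects")
  }
  z0 <- conformations[[1L]]$z
  same <- vapply(conformations, function(cf) identical(cf$z, z0), logical(1))
  if (!all(same)) {
    stop("dataset error: inconsistent atom ordering/composition across frames")
  }
  structure(list(conformations = conformations, name = name,
                 units = c(length = "Angstrom", energy = "kcal/mol")),
            class = "mol_dataset")
}

#' @export
length.mol_dataset <- function(x) length(x$conformations)

#' @export
`[.mol_dataset` <- function(x, i) {
  mol_dataset(x$conformations[i], name = x$name)
}

#' @export
`[[.mol_dataset` <- function(x, i) x$conformations[[i]]

#' @export
print.mol_dataset <- function(x, ...) {
  cf <- x$conformations[[1L]]
  cat(sprintf("<mol_dataset '%s': %d frames, %d atoms [%s], %s energies, %s forces>\n",
              x$name, length(x), length(cf$z),
              paste(z_to_symbols(cf$z), collapse = ""),
              if (is.null(cf$E)) "no" else "with",
              if (is.null(cf$F)) "no" else "with"))
  invisible(x)
}

#' Nuclear charges of a dataset
#' @param dataset A `mol_dataset`.
#' @return Integer vector of nuclear charges shared by all frames.
#' @export
dataset_z <- function(dataset) dataset$conformations[[1L]]$z

#' Energies of all frames
#' @param dataset A `mol_dataset`.
#' @return Numeric vector of energies; errors if any frame lacks one.
#' @export
dataset_energies <- function(dataset) {
  Es <- lapply(dataset$conformations, `[[`, "E")
  if (any(vapply(Es, is.null, logical(1)))) {
    stop("labeling error: not all conformations carry an energy")
  }
  vapply(Es, identity, numeric(1))
}
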