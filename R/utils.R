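# Internal utilities: seeded evaluation, unit constants, element tables.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed` and
#' restores the previous RNG state afterwards, so that no function in the
#' package leaks random state. All stochastic operations in the package take
#' an explicit integer seed and route through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Boltzmann constant in kcal mol^-1 K^-1
.kB <- 1.987204259e-3

# Acceleration conversion: a [Angstrom fs^-2] = F [kcal mol^-1 A^-1] / m [amu]
# times this constant (1 kcal = 4184 J exactly; 1 amu = 1 g mol^-1).
.kcal_accel <- 4.184e-4

# Frequency conversion: nu [cm^-1] = f [fs^-1] * 1e15 / c [cm s^-1]
.per_fs_to_cm1 <- 1e15 / 2.99792458e10

# Element symbols indexed by nuclear charge (first 54 elements)
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

# Standard atomic weights (amu), same indexing
.element_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 97.0, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29)

#' Map element symbols to nuclear charges
#' @param symbols Character vector of element symbols (e.g. "C", "H").
#' @return Integer vector of nuclear charges.
#' @keywords internal
symbols_to_z <- function(symbols) {
  z <- match(symbols, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' Map nuclear charges to element symbols
#' @param z Integer vector of nuclear charges.
#' @return Character vector of element symbols.
#' @keywords internal
z_to_symbols <- function(z) {
  if (any(z < 1L | z > length(.element_symbols))) {
    stop("nuclear charge out of supported range 1..", length(.element_symbols))
  }
  .element_symbols[z]
}

#' Atomic masses for nuclear charges
#' @param z Integer vector of nuclear charges.
#' @return Numeric vector of masses in amu.
#' @export
atomic_masses <- function(z) {
  if (any(z < 1L | z > length(.element_masses))) {
    stop("nuclear charge out of supported range 1..", length(.element_masses))
  }
  .element_masses[z]
}
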