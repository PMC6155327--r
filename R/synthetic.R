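# Synthetic molecular systems: geometry templates with known permutational
# symmetries and analytic toy potentials supplying exact energies and forces.
# These stand in for ab initio MD reference data so that every stage of the
# pipeline (symmetry discovery, training, dynamics) can be validated
# self-contained. Template bond lengths and angles are literature-typical
# idealized values; they are not meant to reproduce any particular level of
# electronic-structure theory.

#' Build a standard molecular geometry template
#'
#' @param name One of `"benzene"`, `"naphthalene"`, `"ethanol"`,
#'   `"malonaldehyde"`.
#' @return A [conformation()] (no energy/force labels).
#' @export
build_geometry <- function(name) {
  switch(name,
    benzene = {
      # planar ring, r(CC) = 1.39, r(CH) = 1.09; C1..C6 then H1..H6
      th <- (0:5) * pi / 3
      RC <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
      RH <- cbind((1.39 + 1.09) * cos(th), (1.39 + 1.09) * sin(th), 0)
      conformation(c(rep(6L, 6L), rep(1L, 6L)), rbind(RC, RH))
    },
    naphthalene = {
      # two fused regular hexagons, r(CC) = 1.40, r(CH) = 1.09;
      # C1..C8 (CH carbons), C9/C10 bridgeheads, then H1..H8 on C1..C8
      a <- 1.40
      u <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
      c1 <- c(sqrt(3) / 2 * a, 0, 0)
      c2 <- -c1
      ang1 <- c(90, 30, -30, -90)          # ring 1 CH positions
      ang2 <- c(-90, -150, 150, 90)        # ring 2 CH positions
      RC <- rbind(t(vapply(ang1, function(d) c1 + a * u(d), numeric(3))),
                  t(vapply(ang2, function(d) c2 + a * u(d), numeric(3))),
                  c(0, a / 2, 0), c(0, -a / 2, 0))
      RH <- rbind(t(vapply(ang1, function(d) c1 + (a + 1.09) * u(d), numeric(3))),
                  t(vapply(ang2, function(d) c2 + (a + 1.09) * u(d), numeric(3))))
      conformation(c(rep(6L, 10L), rep(1L, 8L)), rbind(RC, RH))
    },
    ethanol = {
      # atom order: C(methyl) C O H(O) H(C2) H(C2) H(Me) H(Me) H(Me);
      # staggered Cs template, hydroxyl trans
      entries <- list(
        list(),                                                    # C1
        list(bond = c(1, 1.51)),                                   # C2
        list(bond = c(2, 1.43), angle = c(1, 107.5)),              # O
        list(bond = c(3, 0.96), angle = c(2, 105), dihedral = c(1, 180)),  # H-O
        list(bond = c(2, 1.09), angle = c(1, 110), dihedral = c(3, 120)),  # H-C2
        list(bond = c(2, 1.09), angle = c(1, 110), dihedral = c(3, -120)), # H-C2
        list(bond = c(1, 1.09), angle = c(2, 110), dihedral = c(3, 180)),  # H-Me
        list(bond = c(1, 1.09), angle = c(2, 110), dihedral = c(3, 60)),   # H-Me
        list(bond = c(1, 1.09), angle = c(2, 110), dihedral = c(3, -60)))  # H-Me
      conformation(c(6L, 6L, 8L, 1L, 1L, 1L, 1L, 1L, 1L), zmat_to_cart(entries))
    },
    malonaldehyde = {
      # enol tautomer, planar template with intramolecular O-H...O contact;
      # atom order: C1 C2 C3 O(H) O(=C3) H(O) H(C1) H(C2) H(C3)
      entries <- list(
        list(),                                                    # C1
        list(bond = c(1, 1.40)),                                   # C2
        list(bond = c(2, 1.44), angle = c(1, 120)),                # C3
        list(bond = c(1, 1.32), angle = c(2, 122), dihedral = c(3, 0)),    # O-H
        list(bond = c(3, 1.24), angle = c(2, 124), dihedral = c(1, 0)),    # O=C3
        list(bond = c(4, 0.98), angle = c(1, 105), dihedral = c(2, 0)),    # H(O)
        list(bond = c(1, 1.08), angle = c(2, 118), dihedral = c(3, 180)),  # H(C1)
        list(bond = c(2, 1.08), angle = c(1, 120), dihedral = c(4, 180)),  # H(C2)
        list(bond = c(3, 1.08), angle = c(2, 116), dihedral = c(1, 180)))  # H(C3)
      conformation(c(6L, 6L, 6L, 8L, 8L, 1L, 1L, 1L, 1L), zmat_to_cart(entries))
    },
    stop("argument error: unknown geometry template '", name, "'"))
}

# spring-network + torsion toy potential evaluator (internal)
.toy_eval <- function(pes, R) {
  E <- 0
  G <- matrix(0, nrow(R), 3L)             # gradient of E
  sp <- pes$springs
  if (nrow(sp) > 0L) {
    d <- R[sp$i, , drop = FALSE] - R[sp$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - sp$r0
    E <- E + sum(0.5 * sp$k * dr^2)
    gpair <- (sp$k * dr / r) * d           # dE/dr_i per spring
    for (s in seq_len(nrow(sp))) {
      G[sp$i[s], ] <- G[sp$i[s], ] + gpair[s, ]
      G[sp$j[s], ] <- G[sp$j[s], ] - gpair[s, ]
    }
  }
  for (tor in pes$torsions) {
    dh <- dihedral_angle(R, tor$idx, gradient = TRUE)
    phi <- dh$angle * pi / 180
    E <- E + 0.5 * tor$barrier * (1 - cos(2 * phi)) +
      0.5 * tor$tilt * (1 - cos(phi))
    dVdphi <- tor$barrier * sin(2 * phi) + 0.5 * tor$tilt * sin(phi)
    G[tor$idx, ] <- G[tor$idx, ] + dVdphi * dh$grad
  }
  list(E = E, F = -G)
}

#' Construct an analytic toy potential-energy surface
#'
#' All toys are sums of harmonic pair springs (energy depends only on
#' interatomic distances, hence exactly invariant under permutations of
#' identical atoms and rigid motions), plus an explicit torsion term for the
#' double-well system. Forces are analytic.
#'
#' * `harmonic_dimer`: two carbon atoms with a single bond spring
#'   (params: `k`, `r0`).
#' * `rotor_molecule`: an ethane-like 6-atom system C2H3F whose three
#'   equivalent hydrogens form an exact 3-fold rotor; the barrier height is
#'   set by the `k_rotor` spring between the fluorine and the rotor
#'   hydrogens (params: `k_rotor`).
#' * `double_well_torsion`: an asymmetric 4-atom chain (F-C-C-Cl) with a
#'   torsional double well: minima at 0 and 180 degrees separated by a
#'   configurable `barrier`, offset in energy by `tilt` (kcal/mol).
#'
#' @param name One of `"harmonic_dimer"`, `"rotor_molecule"`,
#'   `"double_well_torsion"`.
#' @param params Named list overriding the defaults described above.
#' @return An object of class `toy_pes` with fields `z`, `template`
#'   (coordinates), `springs`, `torsions`, `syms` (declared permutational
#'   symmetries as reordering vectors, identity first).
#' @export
make_toy_pes <- function(name, params = list()) {
  get_par <- function(key, default) {
    if (!is.null(params[[key]])) {
      v <- params[[key]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
          (key != "tilt" && v <= 0)) {
        stop("argument error: invalid parameter '", key, "'")
      }
      v
    } else default
  }
  pes <- switch(name,
    harmonic_dimer = {
      k <- get_par("k", 200); r0 <- get_par("r0", 1.2)
      list(name = name, z = c(6L, 6L),
           template = matrix(c(0, 0, 0, r0, 0, 0), 2L, 3L, byrow = TRUE),
           springs = data.frame(i = 1L, j = 2L, k = k, r0 = r0),
           torsions = list(),
           syms = list(1:2, 2:1))
    },
    rotor_molecule = {
      k_rotor <- get_par("k_rotor", 5)
      entries <- list(
        list(),                                                   # C1
        list(bond = c(1, 1.50)),                                  # C2
        list(bond = c(1, 1.35), angle = c(2, 110)),               # F on C1
        list(bond = c(2, 1.09), angle = c(1, 110), dihedral = c(3, 60)),
        list(bond = c(2, 1.09), angle = c(1, 110), dihedral = c(3, 180)),
        list(bond = c(2, 1.09), angle = c(1, 110), dihedral = c(3, -60)))
      Rt <- zmat_to_cart(entries)
      dist_t <- function(i, j) sqrt(sum((Rt[i, ] - Rt[j, ])^2))
      fh <- vapply(4:6, function(h) dist_t(3L, h), numeric(1))
      springs <- rbind(
        data.frame(i = c(1L, 1L, 2L, 2L, 2L), j = c(2L, 3L, 4L, 5L, 6L),
                   k = 300, r0 = c(1.50, 1.35, 1.09, 1.09, 1.09)),
        data.frame(i = c(3L, 1L, 1L, 1L), j = c(2L, 4L, 5L, 6L),
                   k = 100, r0 = c(dist_t(3L, 2L), dist_t(1L, 4L),
                                   dist_t(1L, 4L), dist_t(1L, 4L))),
        data.frame(i = c(4L, 4L, 5L), j = c(5L, 6L, 6L),
                   k = 50, r0 = dist_t(4L, 5L)),
        # rotor coupling: identical springs fluorine <-> each rotor hydrogen
        data.frame(i = 3L, j = 4:6, k = k_rotor, r0 = mean(fh)))
      list(name = name, z = c(6L, 6L, 9L, 1L, 1L, 1L),
           template = Rt, springs = springs, torsions = list(),
           syms = list(1:6,
                       c(1L, 2L, 3L, 5L, 6L, 4L),
                       c(1L, 2L, 3L, 6L, 4L, 5L)))
    },
    double_well_torsion = {
      barrier <- get_par("barrier", 1.5)
      tilt <- get_par("tilt", 0.4)
      entries <- list(
        list(),                                                   # F
        list(bond = c(1, 1.35)),                                  # C
        list(bond = c(2, 1.54), angle = c(1, 110)),               # C
        list(bond = c(3, 1.77), angle = c(2, 112), dihedral = c(1, 0)))  # Cl
      Rt <- zmat_to_cart(entries)
      dist_t <- function(i, j) sqrt(sum((Rt[i, ] - Rt[j, ])^2))
      springs <- data.frame(
        i = c(1L, 2L, 3L, 1L, 2L),
        j = c(2L, 3L, 4L, 3L, 4L),
        k = c(300, 300, 300, 80, 80),
        r0 = c(1.35, 1.54, 1.77, dist_t(1L, 3L), dist_t(2L, 4L)))
      list(name = name, z = c(9L, 6L, 6L, 17L),
           template = Rt, springs = springs,
           torsions = list(list(idx = 1:4, barrier = barrier, tilt = tilt)),
           syms = list(1:4))
    },
    stop("argument error: unknown toy PES '", name, "'"))
  class(pes) <- "toy_pes"
  pes
}

#' @export
print.toy_pes <- function(x, ...) {
  cat(sprintf("<toy_pes '%s': %d atoms, %d springs, %d torsion terms, %d declared symmetries>\n",
              x$name, length(x$z), nrow(x$springs), length(x$torsions),
              length(x$syms)))
  invisible(x)
}

#' Evaluate a toy potential
#' @param pes A `toy_pes`.
#' @param R N x 3 coordinate matrix.
#' @return List with scalar `E` (kcal/mol) and N x 3 `F` (kcal/mol/Angstrom).
#' @export
toy_energy_forces <- function(pes, R) {
  stopifnot(inherits(pes, "toy_pes"))
  .toy_eval(pes, as.matrix(R))
}

#' Sample perturbed conformations around a template
#'
#' Emulates thermally perturbed MD snapshots: optional torsion-angle draws
#' (uniform over the full circle, to cross rotational barriers, or Boltzmann
#' at a given temperature from a supplied 1-D torsion potential) followed by
#' independent Gaussian Cartesian noise. When a `toy_pes` is given, exact
#' energy and force labels are attached.
#'
#' @param x A [conformation()] template or a `toy_pes` (whose template is
#'   used and whose analytic potential supplies labels).
#' @param n Number of conformations.
#' @param cartesian_noise Standard deviation of the Gaussian perturbation of
#'   every Cartesian coordinate (Angstrom).
#' @param torsion_sampling Optional list of torsion specs, each a list with
#'   `idx` (4 atom indices), `moving` (atoms rotated), `mode` (`"uniform"`
#'   or `"boltzmann"`), and for Boltzmann mode `potential`, a function of the
#'   angle in degrees returning kcal/mol.
#' @param temperature Temperature (K) for Boltzmann torsion draws.
#' @param seed Integer seed; sampling is bit-reproducible for a fixed seed.
#' @return A [mol_dataset()] of `n` conformations.
#' @export
sample_conformations <- function(x, n, cartesian_noise = 0.05,
                                 torsion_sampling = NULL, temperature = 300,
                                 seed = 0L) {
  n <- as.integer(n)
  if (n < 1L) stop("argument error: n must be >= 1")
  is_pes <- inherits(x, "toy_pes")
  template <- if (is_pes) x$template else x$R
  z <- if (is_pes) x$z else x$z
  # precompute Boltzmann samplers on a 0.25-degree grid
  grids <- lapply(torsion_sampling, function(tor) {
    if (identical(tor$mode, "boltzmann")) {
      phi <- seq(-179.75, 180, by = 0.25)
      w <- exp(-vapply(phi, tor$potential, numeric(1)) / (.kB * temperature))
      list(phi = phi, w = w / sum(w))
    } else NULL
  })
  confs <- with_seed(seed, {
    lapply(seq_len(n), function(frame) {
      R <- template
      if (!is.null(torsion_sampling)) {
        for (t_i in seq_along(torsion_sampling)) {
          tor <- torsion_sampling[[t_i]]
          target <- if (identical(tor$mode, "boltzmann")) {
            g <- grids[[t_i]]
            sample(g$phi, 1L, prob = g$w)
          } else {
            stats::runif(1L, -180, 180)
          }
          R <- set_torsion(R, tor$idx, tor$moving, target)
        }
      }
      if (cartesian_noise > 0) {
        R <- R + matrix(stats::rnorm(length(R), sd = cartesian_noise),
                        nrow(R), 3L)
      }
      if (is_pes) {
        ef <- .toy_eval(x, R)
        conformation(z, R, E = ef$E, F = ef$F)
      } else {
        conformation(z, R)
      }
    })
  })
  mol_dataset(confs, name = if (is_pes) x$name else "sampled")
}
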