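# Geometric primitives: dihedral angles (value and analytic gradient),
# rotations about bonds, and internal-coordinate (z-matrix style) geometry
# construction.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate vector (zero norm)")
  v / n
}

#' Signed dihedral (torsion) angle
#'
#' Returns the signed torsion angle for four atoms in degrees, in the
#' interval (-180, 180], using the atan2 construction on the plane normals.
#'
#' @param R N x 3 coordinate matrix (Angstrom).
#' @param idx Integer vector of 4 distinct atom indices (a, b, c, d); the
#'   angle is measured about the b-c bond.
#' @param gradient If `TRUE`, also return the analytic gradient of the angle
#'   (in radians per Angstrom) with respect to the four atom positions.
#' @return The angle in degrees, or (with `gradient = TRUE`) a list with
#'   `angle` (degrees) and `grad` (4 x 3 matrix, radians/Angstrom).
#' @export
dihedral_angle <- function(R, idx, gradient = FALSE) {
  if (length(idx) != 4L || anyDuplicated(idx)) {
    stop("idx must give 4 distinct atom indices")
  }
  p <- R[idx, , drop = FALSE]
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: collinear atoms about the central bond")
  }
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  phi <- atan2(y, x)                      # radians in (-pi, pi]
  ang <- phi * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (!gradient) return(ang)
  # analytic gradient (radians per Angstrom); standard rigid-rotor result
  g1 <- -(nb2 / sum(n1^2)) * n1
  g4 <- (nb2 / sum(n2^2)) * n2
  c12 <- sum(b1 * b2) / sum(b2^2)
  c32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -g1 - c12 * g1 + c32 * g4
  g3 <- -g4 + c12 * g1 - c32 * g4
  list(angle = ang, grad = rbind(g1, g2, g3, g4, deparse.level = 0))
}

#' Rotate atoms about a bond axis
#'
#' Rotates the atoms in `moving` about the axis through atoms `a` and `b`
#' (right-handed about the unit vector from `a` to `b`) by `angle` degrees.
#'
#' @param R N x 3 coordinate matrix.
#' @param a,b Atom indices defining the axis.
#' @param moving Indices of atoms to rotate.
#' @param angle Rotation angle in degrees.
#' @return The rotated coordinate matrix.
#' @export
rotate_about_bond <- function(R, a, b, moving, angle) {
  u <- .normalize(R[b, ] - R[a, ])
  th <- angle * pi / 180
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)   # column-major: K %*% v = u x v
  Rot <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  origin <- R[b, ]
  R[moving, ] <- sweep(sweep(R[moving, , drop = FALSE], 2L, origin) %*% t(Rot),
                       2L, origin, `+`)
  R
}

#' Set a torsion angle by rotating a group of atoms
#'
#' Rotates `moving` about the idx[2]-idx[3] bond so that the dihedral defined
#' by `idx` becomes `target` degrees.
#'
#' @inheritParams dihedral_angle
#' @param moving Indices of the atoms to rotate (must include `idx[4]`,
#'   must not include `idx[1]`..`idx[3]`).
#' @param target Target dihedral angle in degrees.
#' @return The modified coordinate matrix.
#' @export
set_torsion <- function(R, idx, moving, target) {
  cur <- dihedral_angle(R, idx)
  R2 <- rotate_about_bond(R, idx[2L], idx[3L], moving, target - cur)
  # resolve the handedness of the rotation convention empirically: one of the
  # two senses lands on the target
  ang2 <- dihedral_angle(R2, idx)
  err2 <- abs(((ang2 - target + 180) %% 360) - 180)
  if (err2 > 1e-6) {
    R2 <- rotate_about_bond(R, idx[2L], idx[3L], moving, cur - target)
  }
  R2
}

# Build Cartesian coordinates from internal coordinates (NERF construction).
# `entries` is a list; entry k (k >= 4) is list(bond=c(ref, r),
# angle=c(ref, theta_deg), dihedral=c(ref, phi_deg)). The first three entries
# are placed canonically: atom 1 at the origin, atom 2 along +x, atom 3 in
# the xy-plane using its bond/angle references.
zmat_to_cart <- function(entries) {
  n <- length(entries)
  R <- matrix(0, n, 3L)
  if (n >= 2L) R[2L, ] <- c(entries[[2L]]$bond[2L], 0, 0)
  if (n >= 3L) {
    e <- entries[[3L]]
    ref <- e$bond[1L]; r <- e$bond[2L]
    aref <- e$angle[1L]; th <- e$angle[2L] * pi / 180
    dir <- .normalize(R[aref, ] - R[ref, ])
    # rotate dir by theta in the xy-plane
    rot <- c(dir[1L] * cos(th) - dir[2L] * sin(th),
             dir[1L] * sin(th) + dir[2L] * cos(th), 0)
    R[3L, ] <- R[ref, ] + r * rot
  }
  if (n >= 4L) {
    for (k in 4:n) {
      e <- entries[[k]]
      Cc <- R[e$bond[1L], ]; r <- e$bond[2L]
      Bb <- R[e$angle[1L], ]; th <- e$angle[2L] * pi / 180
      Aa <- R[e$dihedral[1L], ]; ph <- e$dihedral[2L] * pi / 180
      bc <- .normalize(Cc - Bb)
      ab <- Bb - Aa
      nrm <- .normalize(.cross3(ab, bc))
      m <- .cross3(nrm, bc)
      d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
      R[k, ] <- Cc + d2[1L] * bc + d2[2L] * m + d2[3L] * nrm
    }
  }
  R
}
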