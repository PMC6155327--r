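# Geometry descriptor: the vector of inverse interatomic distances in fixed
# upper-triangle pair order, with its analytic Jacobian with respect to the
# 3N Cartesian coordinates (atom-major stacking x1 y1 z1 x2 y2 z2 ...).
# The descriptor is invariant under rigid rotations and translations, which
# makes every kernel value built on it invariant too.

# fixed pair order: (1,2), (1,3), ..., (1,N), (2,3), ... (combn order)
pair_table <- function(n) t(utils::combn(n, 2L))

# rank of pair (i, j), i < j, in the fixed order
pair_rank <- function(i, j, n) {
  (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i)
}

#' Inverse-distance descriptor of a geometry
#'
#' @param R N x 3 coordinate matrix (Angstrom).
#' @return An object of class `descriptor`: list with `D` (length
#'   N(N-1)/2 vector of inverse pairwise distances, 1/Angstrom), `J`
#'   (analytic Jacobian, N(N-1)/2 x 3N, 1/Angstrom^2) and `n_atoms`.
#' @export
descriptor <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  pairs <- pair_table(n)
  diffs <- R[pairs[, 1L], , drop = FALSE] - R[pairs[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(diffs^2))
  if (any(r < 1e-10)) stop("singular descriptor: coincident atoms")
  D <- 1 / r
  # dD_k/dr_i = -(r_i - r_j)/r^3 ; dD_k/dr_j = +(r_i - r_j)/r^3
  gp <- -diffs / r^3
  d <- length(D)
  J <- matrix(0, d, 3L * n)
  k_idx <- rep(seq_len(d), each = 3L)
  # column indices of atoms i and j for each pair, component-major
  ci <- as.vector(vapply(pairs[, 1L], function(a) 3L * (a - 1L) + 1:3, integer(3)))
  cj <- as.vector(vapply(pairs[, 2L], function(a) 3L * (a - 1L) + 1:3, integer(3)))
  J[cbind(k_idx, ci)] <- as.vector(t(gp))
  J[cbind(k_idx, cj)] <- -as.vector(t(gp))
  structure(list(D = D, J = J, n_atoms = n), class = "descriptor")
}

# descriptor-space index map of a reordering s (geometry R -> R[s, ]):
# descriptor(R[s, ])$D == descriptor(R)$D[map]
pair_perm_map <- function(s, n = length(s)) {
  pairs <- pair_table(n)
  i2 <- s[pairs[, 1L]]
  j2 <- s[pairs[, 2L]]
  lo <- pmin(i2, j2)
  hi <- pmax(i2, j2)
  pair_rank(lo, hi, n)
}

#' Apply an atom permutation to a descriptor
#'
#' Computes the descriptor of the permuted geometry `R[s, ]` by exact index
#' remapping of the pair entries and Jacobian rows/columns, without
#' recomputing distances.
#'
#' @param s Integer reordering vector (geometry relabeling `R[s, ]`).
#' @param desc A [descriptor()].
#' @return The descriptor of the permuted geometry.
#' @export
permute_descriptor <- function(s, desc) {
  stopifnot(inherits(desc, "descriptor"), is_perm(s),
            length(s) == desc$n_atoms)
  s <- as.integer(s)
  map <- pair_perm_map(s)
  cols <- as.vector(vapply(s, function(a) 3L * (a - 1L) + 1:3, integer(3)))
  structure(list(D = desc$D[map], J = desc$J[map, cols, drop = FALSE],
                 n_atoms = desc$n_atoms),
            class = "descriptor")
}
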