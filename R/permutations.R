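# Permutation bookkeeping. A permutation is stored as an integer "reordering"
# vector s of length N: applying it to a geometry gives R[s, ], i.e. atom k
# of the permuted geometry is atom s[k] of the original. A "mapping" view
# (atom a of frame G corresponds to atom tau[a] of frame H) is used by the
# matching code; the two are related by inversion.

#' Identity permutation
#' @param n Length.
#' @return The integer vector `1:n`.
#' @export
perm_identity <- function(n) seq_len(n)

#' Test whether a vector is a permutation of 1..N
#' @param p Vector to test.
#' @return `TRUE` if `p` contains each of `1..length(p)` exactly once.
#' @export
is_perm <- function(p) {
  is.numeric(p) && length(p) >= 1L && !anyNA(p) &&
    identical(sort(as.integer(p)), seq_along(p))
}

#' Invert a permutation
#' @param p Integer permutation vector.
#' @return The inverse permutation.
#' @export
perm_inverse <- function(p) {
  ip <- integer(length(p))
  ip[p] <- seq_along(p)
  ip
}

#' Compose two permutations (mapping view)
#'
#' `(perm_compose(q, p))[a] = q[p[a]]`: apply `p` first, then `q`.
#'
#' @param q,p Integer permutation vectors.
#' @return The composed permutation.
#' @export
perm_compose <- function(q, p) q[p]

#' Apply a reordering to a conformation
#'
#' Relabels the atoms of a [conformation()]: `R -> R[s, ]`, with charges and
#' forces following their atoms.
#'
#' @param conf A [conformation()].
#' @param s Integer reordering vector.
#' @return The relabeled conformation.
#' @export
apply_perm <- function(conf, s) {
  conformation(conf$z[s], conf$R[s, , drop = FALSE], E = conf$E,
               F = if (!is.null(conf$F)) conf$F[s, , drop = FALSE] else NULL)
}

#' Block permutation matrix of a reordering
#'
#' The 3N x 3N permutation matrix acting on atom-major stacked coordinates
#' (x1 y1 z1 x2 y2 z2 ...): `P %*% x` is the stacked coordinate vector of
#' `R[s, ]`. Intended for reference computations and test oracles.
#'
#' @param s Integer reordering vector.
#' @return 3N x 3N 0/1 matrix.
#' @export
perm_matrix_3n <- function(s) {
  n <- length(s)
  P <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(n)) {
    rows <- 3L * (k - 1L) + 1:3
    cols <- 3L * (s[k] - 1L) + 1:3
    P[cbind(rows, cols)] <- 1
  }
  P
}

#' All permutations of 1..n
#'
#' Lexicographic enumeration, for brute-force oracles and small-n searches
#' only (n! rows).
#'
#' @param n Number of elements (keep small).
#' @return An n! x n integer matrix, one permutation per row.
#' @export
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub), n - 1L),
                            deparse.level = 0))
  }
  out
}

#' Number of index permutations of a molecule
#'
#' Counts the ways the atoms of a molecule can be relabeled without mapping
#' different elements onto each other: the product of factorials of the
#' per-element atom counts. For benzene (C6H6) this is 6! * 6! = 518400.
#'
#' @param z Integer vector of nuclear charges.
#' @return The (possibly huge) count as a double.
#' @export
count_index_permutations <- function(z) {
  prod(factorial(as.numeric(table(z))))
}
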