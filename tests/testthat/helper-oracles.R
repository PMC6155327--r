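# Shared test oracles and fixture builders. Everything is generated in code;
# no data files are read.

# central finite-difference gradient of a scalar function of a flat vector
fd_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# independent dihedral implementation (acos magnitude + triple-product sign),
# structurally different from the atan2 form in the package
dihedral_oracle <- function(R, idx) {
  b1 <- R[idx[2], ] - R[idx[1], ]
  b2 <- R[idx[3], ] - R[idx[2], ]
  b3 <- R[idx[4], ] - R[idx[3], ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) phi <- -phi
  if (phi <= -180) phi <- phi + 360
  phi
}

# random well-separated geometry (avoids near-coincident atoms)
rand_geom <- function(n, sd = 2) {
  repeat {
    R <- matrix(stats::rnorm(3 * n, sd = sd), n, 3)
    if (min(stats::dist(R)) > 0.5) return(R)
  }
}

# all exact automorphisms of a distance matrix that respect the charges,
# found by backtracking with row-multiset pruning (test-only oracle)
distance_automorphisms <- function(A, z, tol = 1e-6) {
  n <- nrow(A)
  out <- list()
  assign_next <- function(s) {
    k <- length(s) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- as.integer(s)
      return(invisible(NULL))
    }
    for (cand in setdiff(seq_len(n), s)) {
      if (z[cand] != z[k]) next
      ok <- TRUE
      for (j in seq_along(s)) {
        if (abs(A[s[j], cand] - A[j, k]) > tol) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(s, cand))
    }
  }
  assign_next(integer(0))
  out
}

# brute-force minimum assignment cost over all n! permutations; when charges
# are supplied only charge-respecting assignments compete (matching G atom a
# to H atom p[a] requires z_G[a] == z_H[p[a]])
exhaustive_min_cost <- function(A_G, A_H, z_G = NULL, z_H = NULL) {
  perms <- all_permutations(nrow(A_G))
  if (!is.null(z_G)) {
    valid <- apply(perms, 1, function(p) all(z_G == z_H[p]))
    perms <- perms[valid, , drop = FALSE]
  }
  min(apply(perms, 1, function(p) assignment_cost(A_G, A_H, p)))
}

# ideal benzene adjacency (template) for automorphism checks
benzene_template_adjacency <- function() adjacency_matrix(build_geometry("benzene"))

# is tau (mapping view) an automorphism of the ideal template adjacency?
is_template_automorphism <- function(A0, tau, tol = 1e-6) {
  inv <- perm_inverse(tau)
  max(abs(A0[inv, inv] - A0)) < tol
}

# ethanol full-circle torsion sampling spec shared by several tests
ethanol_torsion_spec <- function() {
  list(list(idx = c(1, 2, 3, 4), moving = 4L, mode = "uniform"),
       list(idx = c(3, 2, 1, 7), moving = 7:9, mode = "uniform"))
}

# rotor-toy torsion sampling spec
rotor_torsion_spec <- function() {
  list(list(idx = c(3, 1, 2, 4), moving = 4:6, mode = "uniform"))
}
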