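# Data-driven discovery of permutational molecular symmetries.
#
# Pipeline: pairwise matching of conformations via the overlap of adjacency
# (interatomic distance) matrix eigenvectors solved as a linear assignment
# problem with a nuclear-charge penalty; global synchronization of the
# pairwise assignments through the transitive closure of the minimum
# spanning tree of matching costs; canonicalization of all geometries to a
# reference ordering; and collection of the unique relabelings that relate
# canonicalized geometries -- the physically realized permutational
# symmetries of the sampled ensemble.

#' Interatomic distance (adjacency) matrix
#'
#' @param x A [conformation()] or an N x 3 coordinate matrix.
#' @return N x N symmetric matrix of Euclidean interatomic distances
#'   (Angstrom), zero diagonal.
#' @export
adjacency_matrix <- function(x) {
  R <- if (inherits(x, "conformation")) x$R else as.matrix(x)
  if (!all(is.finite(R))) stop("coordinates must be finite")
  A <- as.matrix(stats::dist(R))
  dimnames(A) <- NULL
  if (nrow(A) > 1L) {
    off <- A[upper.tri(A)]
    if (any(off < 1e-8)) {
      warning("degenerate geometry: two atoms at (nearly) identical positions")
    }
  }
  A
}

#' Eigenvector overlap of two adjacency matrices
#'
#' Computes the eigendecompositions of both matrices (eigenvalues sorted
#' ascending) and the overlap matrix `M = abs(U_G) %*% t(abs(U_H))`, whose
#' negative is the assignment cost for the matching step. Taking absolute
#' values of the eigenvector entries resolves their sign ambiguity. For
#' (nearly) degenerate spectra a deterministic symmetric jitter of relative
#' size 1e-9 is added before decomposition to pin down the eigenbasis.
#'
#' @param A_G,A_H N x N symmetric adjacency matrices.
#' @return A list (matching workspace) with `U_G`, `U_H` (eigenvector
#'   matrices, columns in ascending eigenvalue order), `M_overlap`, and
#'   `C_M = -M_overlap`.
#' @export
eigen_overlap <- function(A_G, A_H) {
  A_G <- as.matrix(A_G); A_H <- as.matrix(A_H)
  n <- nrow(A_G)
  if (!isTRUE(all.equal(dim(A_G), dim(A_H))) || ncol(A_G) != n) {
    stop("argument error: adjacency matrices must be square and same size")
  }
  if (max(abs(A_G - t(A_G))) > 1e-9 || max(abs(A_H - t(A_H))) > 1e-9) {
    stop("argument error: adjacency matrices must be symmetric")
  }
  decomp <- function(A) {
    scale <- max(abs(A), 1)
    e <- eigen(A, symmetric = TRUE)
    vals <- rev(e$values)                  # ascending
    if (n > 1L && min(diff(vals)) < 1e-8 * scale) {
      # deterministic symmetric jitter to break exact degeneracy
      jit <- with_seed(7919L * n + 13L, matrix(stats::rnorm(n * n), n, n))
      jit <- (jit + t(jit)) * (0.5e-9 * scale)
      e <- eigen(A + jit, symmetric = TRUE)
    }
    e$vectors[, rev(seq_len(n)), drop = FALSE]   # ascending eigenvalue order
  }
  U_G <- decomp(A_G)
  U_H <- decomp(A_H)
  M <- abs(U_G) %*% t(abs(U_H))
  list(U_G = U_G, U_H = U_H, M_overlap = M, C_M = -M)
}

#' Nuclear-charge penalty matrix
#'
#' Entry (i, j) is `abs(z_i - z_j) * epsilon`; added to the assignment cost
#' it prevents matching non-identical nuclei for sufficiently large epsilon.
#'
#' @param z Integer vector of nuclear charges.
#' @param epsilon Penalty weight (> 0).
#' @return N x N penalty matrix.
#' @export
charge_penalty <- function(z, epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  abs(outer(as.numeric(z), as.numeric(z), `-`)) * epsilon
}

#' Optimal atom assignment between two conformations
#'
#' Finds the atom relabeling minimizing the squared Frobenius distance
#' between the two adjacency matrices. The linear assignment problem on the
#' cost matrix `C = -M_overlap + C_z` (eigenvector overlap plus charge
#' penalty, solved with the Hungarian method) provides the initial
#' assignment; because the overlap surrogate is unreliable when the
#' adjacency spectrum has (near-)degenerate eigenvalue clusters -- the
#' eigenbasis inside a cluster is arbitrary -- the assignment is then
#' refined directly against the true objective by iterated linear
#' assignment on its linearization around the current assignment, followed
#' by a charge-preserving pairwise-swap descent. An additional refinement
#' pass started from the identity assignment (when the charge orders agree)
#' guards against poor surrogate initializations; the lower-cost result
#' wins. The reported `cost` is the squared adjacency distance of the
#' returned assignment.
#'
#' @param conf_G,conf_H Two [conformation()]s with the same charge multiset.
#' @param epsilon Charge-penalty weight; default `100 * max(A)` over both
#'   adjacency matrices, large enough that cross-element assignment can
#'   never be optimal.
#' @return A pair assignment: list with `tau` (integer mapping, atom `a` of
#'   G corresponds to atom `tau[a]` of H), `cost` (Angstrom^2), `i`, `j`
#'   (conformation indices, `NA` outside a matching graph).
#' @export
bipartite_match <- function(conf_G, conf_H, epsilon = NULL) {
  stopifnot(inherits(conf_G, "conformation"), inherits(conf_H, "conformation"))
  if (length(conf_G$z) != length(conf_H$z) ||
      !identical(sort(conf_G$z), sort(conf_H$z))) {
    stop("matching error: charge multisets differ")
  }
  A_G <- adjacency_matrix(conf_G)
  A_H <- adjacency_matrix(conf_H)
  if (is.null(epsilon)) epsilon <- 100 * max(A_G, A_H)
  ws <- eigen_overlap(A_G, A_H)
  Cz <- charge_penalty_pair(conf_G$z, conf_H$z, epsilon)
  C <- ws$C_M + Cz
  C <- C - min(C)                          # LSAP requires non-negative costs
  tau0 <- as.integer(clue::solve_LSAP(C))
  best <- .refine_assignment(A_G, A_H, tau0, Cz, conf_G$z, conf_H$z)
  if (identical(conf_G$z, conf_H$z)) {
    alt <- .refine_assignment(A_G, A_H, perm_identity(nrow(A_G)), Cz,
                              conf_G$z, conf_H$z)
    if (alt$cost < best$cost) best <- alt
  }
  list(tau = best$tau, cost = best$cost, i = NA_integer_, j = NA_integer_)
}

# Iterated linear assignment on the linearization of the exact objective
# L(tau) = || A_G[inv, inv] - A_H ||^2 around the current assignment:
# assigning G atom a to H atom b, with all other atoms held at tau,
# contributes sum_{a'} (A_G[a, a'] - A_H[b, tau[a']])^2, which is a linear
# assignment cost. Iterate to a fixed point (cycle-safe), then descend by
# pairwise swaps that preserve the charge matching.
.refine_assignment <- function(A_G, A_H, tau, Cz, z_G, z_H, max_iter = 50L) {
  best_tau <- tau
  best_cost <- assignment_cost(A_G, A_H, tau)
  seen <- paste(tau, collapse = ",")
  rG2 <- rowSums(A_G^2)
  for (it in seq_len(max_iter)) {
    AHp <- A_H[, tau, drop = FALSE]        # column a' compares to H atom tau[a']
    C <- outer(rG2, rowSums(AHp^2), `+`) - 2 * tcrossprod(A_G, AHp)
    C <- C + Cz
    C <- C - min(C)
    tau <- as.integer(clue::solve_LSAP(C))
    cost <- assignment_cost(A_G, A_H, tau)
    if (cost < best_cost) {
      best_cost <- cost
      best_tau <- tau
    }
    key <- paste(tau, collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
  }
  .swap_descent(A_G, A_H, best_tau, best_cost, z_G, z_H)
}

# steepest-admissible pairwise-swap descent on the exact objective; a swap
# of the targets of G atoms a, b is admissible only if it keeps every atom
# matched to an equal nuclear charge
.swap_descent <- function(A_G, A_H, tau, cost, z_G, z_H) {
  n <- length(tau)
  repeat {
    improved <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (z_H[tau[b]] != z_G[a] || z_H[tau[a]] != z_G[b]) next
        cand <- tau
        cand[c(a, b)] <- tau[c(b, a)]
        cand_cost <- assignment_cost(A_G, A_H, cand)
        if (cand_cost < cost - 1e-14) {
          tau <- cand
          cost <- cand_cost
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(tau = tau, cost = cost)
}

# penalty for matching atom i of G to atom j of H (charges may be ordered
# differently in the two frames)
charge_penalty_pair <- function(z_G, z_H, epsilon) {
  abs(outer(as.numeric(z_G), as.numeric(z_H), `-`)) * epsilon
}

#' Adjacency-matrix cost of an assignment
#'
#' The squared Frobenius norm `|| P A_G P^T - A_H ||^2` for the permutation
#' realizing `tau` (atom `a` of G matched to atom `tau[a]` of H).
#'
#' @param A_G,A_H Adjacency matrices.
#' @param tau Integer assignment mapping.
#' @return Scalar cost (Angstrom^2).
#' @export
assignment_cost <- function(A_G, A_H, tau) {
  inv <- perm_inverse(tau)
  sum((A_G[inv, inv] - A_H)^2)
}

#' Build a pairwise matching graph over a dataset
#'
#' Runs [bipartite_match()] for the requested conformation pairs.
#'
#' @param dataset A [mol_dataset()].
#' @param pairs Two-column integer matrix of conformation index pairs
#'   (i < j); default all pairs.
#' @param epsilon Charge-penalty weight passed to [bipartite_match()].
#' @return A `matching_graph`: list with `n`, `pairs` (data frame i, j,
#'   cost), `taus` (list of assignments, aligned with `pairs` rows), and
#'   empty synchronization fields.
#' @export
match_dataset <- function(dataset, pairs = NULL, epsilon = NULL) {
  M <- length(dataset)
  if (M < 2L) stop("need at least 2 conformations")
  if (is.null(pairs)) pairs <- t(utils::combn(M, 2L))
  taus <- vector("list", nrow(pairs))
  cost <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pa <- bipartite_match(dataset[[pairs[k, 1L]]], dataset[[pairs[k, 2L]]],
                          epsilon = epsilon)
    taus[[k]] <- pa$tau
    cost[k] <- pa$cost
  }
  structure(list(n = M,
                 pairs = data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                    cost = cost),
                 taus = taus,
                 tree_edges = NULL, tau_to_ref = NULL, synchronized = NULL),
            class = "matching_graph")
}

# Kruskal MST with explicit (cost, i, j) lexicographic tie-break; returns
# row indices of the tree edges in mg$pairs. A hand-rolled union-find is
# used because the tie-break order is part of the contract.
.kruskal_mst <- function(mg) {
  ord <- order(mg$pairs$cost, mg$pairs$i, mg$pairs$j)
  parent <- seq_len(mg$n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  tree <- integer(0)
  for (k in ord) {
    ra <- find(mg$pairs$i[k]); rb <- find(mg$pairs$j[k])
    if (ra != rb) {
      parent[ra] <- rb
      tree <- c(tree, k)
      if (length(tree) == mg$n - 1L) break
    }
  }
  if (length(tree) != mg$n - 1L) {
    stop("synchronization error: matching graph is disconnected")
  }
  tree
}

#' Synchronize pairwise assignments over the minimum spanning tree
#'
#' Builds the MST of the matching costs (Kruskal, ties broken by (i, j)
#' order) and replaces every pairwise assignment by the composition of
#' tree-edge assignments along the unique tree path, which makes the whole
#' set exactly transitive: `tau_jk o tau_ij = tau_ik` for all triples.
#'
#' @param mg A `matching_graph` from [match_dataset()].
#' @return The graph with `tree_edges` (data frame i, j, cost),
#'   `tau_to_ref` (list: assignment of every conformation to conformation
#'   1), and `synchronized` (list of consistent assignments aligned with
#'   `pairs` rows).
#' @export
synchronize <- function(mg) {
  stopifnot(inherits(mg, "matching_graph"))
  tree <- .kruskal_mst(mg)
  # adjacency list of the tree with directed taus
  adj <- vector("list", mg$n)
  for (k in tree) {
    i <- mg$pairs$i[k]; j <- mg$pairs$j[k]; tau <- mg$taus[[k]]
    adj[[i]] <- c(adj[[i]], list(list(to = j, tau = tau)))
    adj[[j]] <- c(adj[[j]], list(list(to = i, tau = perm_inverse(tau))))
  }
  # BFS from conformation 1: tau_to_ref[[v]] maps atoms of v to atoms of 1
  n_atoms <- length(mg$taus[[1L]])
  tau_to_ref <- vector("list", mg$n)
  tau_to_ref[[1L]] <- perm_identity(n_atoms)
  queue <- 1L
  visited <- c(TRUE, rep(FALSE, mg$n - 1L))
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (edge in adj[[v]]) {
      w <- edge$to
      if (!visited[w]) {
        visited[w] <- TRUE
        # atoms of w -> atoms of v -> atoms of 1
        tau_to_ref[[w]] <- perm_compose(tau_to_ref[[v]], perm_inverse(edge$tau))
        queue <- c(queue, w)
      }
    }
  }
  # synchronized tau_ij = tau_{1j} o tau_{i1}: exact transitivity by
  # construction (integer composition through the reference frame)
  synchronized <- vector("list", nrow(mg$pairs))
  for (k in seq_len(nrow(mg$pairs))) {
    i <- mg$pairs$i[k]; j <- mg$pairs$j[k]
    synchronized[[k]] <- perm_compose(perm_inverse(tau_to_ref[[j]]),
                                      tau_to_ref[[i]])
  }
  mg$tree_edges <- mg$pairs[tree, , drop = FALSE]
  mg$tau_to_ref <- tau_to_ref
  mg$synchronized <- synchronized
  mg
}

# choose the evaluated pairs: all M(M-1)/2 when M <= 100, otherwise a seeded
# random subset of max_pairs kept connected through the chain (i, i+1)
.select_pairs <- function(M, max_pairs, seed) {
  all_pairs <- t(utils::combn(M, 2L))
  if (M <= 100L || nrow(all_pairs) <= max_pairs) return(all_pairs)
  chain <- cbind(seq_len(M - 1L), 2:M)
  chain_keys <- paste(chain[, 1L], chain[, 2L])
  keys <- paste(all_pairs[, 1L], all_pairs[, 2L])
  extra_rows <- which(!(keys %in% chain_keys))
  n_extra <- max(0L, max_pairs - nrow(chain))
  pick <- with_seed(seed, sample(extra_rows, min(n_extra, length(extra_rows))))
  rbind(chain, all_pairs[sort(pick), , drop = FALSE])
}

#' Recover the permutational symmetry set of a conformational ensemble
#'
#' Matches conformation pairs, synchronizes the assignments over the MST,
#' transforms all geometries to the canonical (reference) ordering, and
#' collects the unique relabelings that the raw pairwise matches induce
#' between canonicalized geometries. A candidate permutation is kept when
#' the adjacency cost of the pair that produced it is at most
#' `cost_factor` times the median cost of pairs whose induced permutation
#' is the identity; this filters spurious matches caused by large thermal
#' distortion. The identity is always included and listed first. The
#' recovered set is not required to be closed under composition.
#'
#' @param dataset A [mol_dataset()] with at least 2 conformations (a
#'   single-conformation dataset yields the identity with a warning).
#' @param epsilon Charge-penalty weight (default `100 * max(A)` per pair).
#' @param max_pairs Pair budget when the dataset has more than 100 frames.
#' @param seed Seed for the pair subset draw.
#' @param cost_factor Acceptance threshold multiplier (default 2).
#' @return A `symmetry_set`: list with `perms` (list of reordering vectors
#'   `s`, geometry relabeling `R[s, ]`, identity first), `source_costs`
#'   (minimum adjacency cost of a pair supporting each permutation;
#'   `0` for the identity), `n_atoms`, and `tau_to_ref` (canonicalizing
#'   assignments, for [canonicalize_dataset()]).
#' @export
extract_symmetries <- function(dataset, epsilon = NULL, max_pairs = 5000L,
                               seed = 0L, cost_factor = 2) {
  stopifnot(inherits(dataset, "mol_dataset"))
  M <- length(dataset)
  n_atoms <- length(dataset_z(dataset))
  if (M < 2L) {
    warning("dataset has a single conformation: returning the identity only")
    return(structure(list(perms = list(perm_identity(n_atoms)),
                          source_costs = 0, n_atoms = n_atoms,
                          tau_to_ref = list(perm_identity(n_atoms))),
                     class = "symmetry_set"))
  }
  pairs <- .select_pairs(M, max_pairs, seed)
  mg <- match_dataset(dataset, pairs = pairs, epsilon = epsilon)
  mg <- synchronize(mg)
  # express every raw pairwise match between the canonicalized geometries:
  # sigma = tau_{j->1} o tau_raw(i->j) o tau_{1->i}
  np <- nrow(mg$pairs)
  sig_keys <- character(np)
  sigmas <- vector("list", np)
  for (k in seq_len(np)) {
    i <- mg$pairs$i[k]; j <- mg$pairs$j[k]
    sigma <- perm_compose(mg$tau_to_ref[[j]],
                          perm_compose(mg$taus[[k]],
                                       perm_inverse(mg$tau_to_ref[[i]])))
    sigmas[[k]] <- sigma
    sig_keys[k] <- paste(sigma, collapse = ",")
  }
  id_key <- paste(perm_identity(n_atoms), collapse = ",")
  id_costs <- mg$pairs$cost[sig_keys == id_key]
  med <- if (length(id_costs) > 0L) stats::median(id_costs)
         else stats::median(mg$pairs$cost)
  keep <- mg$pairs$cost <= cost_factor * med
  z <- dataset_z(dataset)
  perms <- list(perm_identity(n_atoms))
  costs <- 0
  seen <- id_key
  for (key in unique(sig_keys[keep])) {
    if (key == id_key) next
    rows <- which(sig_keys == key & keep)
    sigma <- sigmas[[rows[1L]]]
    cost <- min(mg$pairs$cost[rows])
    # each unordered pair supports the relabeling in both directions: if
    # sigma relates canonical i to canonical j, its inverse relates j to i
    # at the same adjacency cost
    for (sg in list(sigma, perm_inverse(sigma))) {
      kk <- paste(sg, collapse = ",")
      if (kk %in% seen) next
      seen <- c(seen, kk)
      s <- perm_inverse(sg)                # mapping -> reordering convention
      if (!identical(z[s], z)) next        # never map unequal nuclei
      perms <- c(perms, list(s))
      costs <- c(costs, cost)
    }
  }
  structure(list(perms = perms, source_costs = costs, n_atoms = n_atoms,
                 tau_to_ref = mg$tau_to_ref),
            class = "symmetry_set")
}

#' @export
print.symmetry_set <- function(x, ...) {
  cat(sprintf("<symmetry_set: S = %d permutations of %d atoms>\n",
              length(x$perms), x$n_atoms))
  invisible(x)
}

#' @export
length.symmetry_set <- function(x) length(x$perms)

#' Identity-only symmetry set
#'
#' Convenience constructor for the degenerate symmetrization (plain,
#' non-symmetric gradient-domain model).
#'
#' @param n_atoms Number of atoms.
#' @return A `symmetry_set` containing only the identity.
#' @export
identity_symmetry <- function(n_atoms) {
  structure(list(perms = list(perm_identity(n_atoms)), source_costs = 0,
                 n_atoms = n_atoms, tau_to_ref = NULL),
            class = "symmetry_set")
}

#' Symmetry set from explicit permutations
#'
#' @param perms List of reordering vectors (each applied as `R[s, ]`); the
#'   identity is prepended if absent.
#' @return A `symmetry_set`.
#' @export
symmetry_set <- function(perms) {
  stopifnot(length(perms) >= 1L, all(vapply(perms, is_perm, logical(1))))
  n_atoms <- length(perms[[1L]])
  keys <- vapply(perms, paste, character(1), collapse = ",")
  perms <- perms[!duplicated(keys)]
  id_key <- paste(perm_identity(n_atoms), collapse = ",")
  if (!(id_key %in% keys)) {
    perms <- c(list(perm_identity(n_atoms)), perms)
  } else {
    # move identity first
    keys <- vapply(perms, paste, character(1), collapse = ",")
    perms <- c(perms[keys == id_key], perms[keys != id_key])
  }
  structure(list(perms = lapply(perms, as.integer),
                 source_costs = rep(NA_real_, length(perms)),
                 n_atoms = n_atoms, tau_to_ref = NULL),
            class = "symmetry_set")
}

#' Reorder all conformations into the canonical atom ordering
#'
#' Applies the synchronized assignment of every conformation to the
#' reference (first) conformation, so that atom `k` means the same physical
#' atom in every frame. Datasets whose frames already share a consistent
#' ordering are returned unchanged (up to that consistent relabeling).
#'
#' @param dataset A [mol_dataset()].
#' @param syms Optional `symmetry_set` from [extract_symmetries()] carrying
#'   `tau_to_ref`; when missing, matching and synchronization are run here.
#' @param epsilon,max_pairs,seed Passed to the matching step when needed.
#' @return The canonicalized [mol_dataset()].
#' @export
canonicalize_dataset <- function(dataset, syms = NULL, epsilon = NULL,
                                 max_pairs = 5000L, seed = 0L) {
  stopifnot(inherits(dataset, "mol_dataset"))
  if (length(dataset) < 2L) return(dataset)
  tau_to_ref <- if (!is.null(syms) && !is.null(syms$tau_to_ref)) {
    syms$tau_to_ref
  } else {
    mg <- match_dataset(dataset,
                        pairs = .select_pairs(length(dataset), max_pairs, seed),
                        epsilon = epsilon)
    synchronize(mg)$tau_to_ref
  }
  confs <- lapply(seq_along(tau_to_ref), function(i) {
    # atom a of frame i is atom tau[a] of the reference: the canonical frame
    # lists atoms in reference order
    apply_perm(dataset[[i]], perm_inverse(tau_to_ref[[i]]))
  })
  mol_dataset(confs, name = dataset$name)
}
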