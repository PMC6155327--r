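test_that("adjacency_matrix matches a direct double loop and is covariant", {
  set.seed(701)
  R <- rand_geom(5)
  A <- adjacency_matrix(R)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(A[i, j], sqrt(sum((R[i, ] - R[j, ])^2)), tolerance = 1e-14)
  }
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  s <- sample(5)
  expect_equal(adjacency_matrix(R[s, ]), A[s, s], tolerance = 1e-14)
  expect_warning(adjacency_matrix(rbind(c(0, 0, 0), c(0, 0, 0))), "degenerate")
})

test_that("eigen_overlap has unit diagonal for equal inputs and bounded entries", {
  set.seed(702)
  A <- adjacency_matrix(rand_geom(6))
  ws <- eigen_overlap(A, A)
  expect_equal(diag(ws$M_overlap), rep(1, 6), tolerance = 1e-10)
  B <- adjacency_matrix(rand_geom(6))
  ws2 <- eigen_overlap(A, B)
  expect_true(all(ws2$M_overlap >= -1e-12 & ws2$M_overlap <= 1 + 1e-12))
  expect_equal(ws2$C_M, -ws2$M_overlap)
  Abad <- A; Abad[1, 2] <- Abad[1, 2] + 1
  expect_error(eigen_overlap(Abad, B), "symmetric")
})

test_that("charge penalty follows the formula and blocks cross-element matches", {
  expect_equal(charge_penalty(c(1, 6), 10), rbind(c(0, 50), c(50, 0)))
  expect_equal(charge_penalty(c(1, 1, 1), 5), matrix(0, 3, 3))
  # methane-like: with a large penalty no optimal assignment maps H onto C
  set.seed(703)
  z <- c(6L, 1L, 1L, 1L, 1L)
  R1 <- rand_geom(5)
  R2 <- rand_geom(5)
  A1 <- adjacency_matrix(R1); A2 <- adjacency_matrix(R2)
  eps <- 100 * max(A1, A2)
  ws <- eigen_overlap(A1, A2)
  C <- ws$C_M + charge_penalty(z, eps)
  # exhaustive check: every assignment mixing H and C costs more than any
  # charge-respecting assignment
  perms <- all_permutations(5)
  costs <- apply(perms, 1, function(p) sum(C[cbind(1:5, p)]))
  mixes <- apply(perms, 1, function(p) any(z[p] != z))
  expect_gt(min(costs[mixes]), max(costs[!mixes]))
})

test_that("bipartite_match recovers exact relabelings with zero cost", {
  set.seed(704)
  z <- c(6L, 6L, 1L, 1L)
  R <- rand_geom(4)
  cf <- conformation(z, R)
  self <- bipartite_match(cf, cf)
  expect_identical(self$tau, 1:4)
  expect_lt(self$cost, 1e-18)
  # known relabeling: R2 = R[s, ] means G atom a sits at H row inv(s)[a]
  s <- c(2L, 1L, 4L, 3L)
  cf2 <- conformation(z[s], R[s, ])
  pa <- bipartite_match(cf, cf2)
  expect_lt(pa$cost, 1e-18)
  expect_identical(pa$tau, perm_inverse(s))
  A_G <- adjacency_matrix(cf); A_H <- adjacency_matrix(cf2)
  expect_equal(pa$cost, exhaustive_min_cost(A_G, A_H), tolerance = 1e-15)
  expect_error(bipartite_match(cf, conformation(c(6L, 6L, 1L, 8L), R)),
               "charge multisets")
})

test_that("bipartite_match equals the exhaustive N! minimum on random fixtures", {
  set.seed(705)
  n_fixture <- 200
  for (fix in seq_len(n_fixture)) {
    n <- sample(3:7, 1)
    z <- sample(c(1L, 6L, 8L), n, replace = TRUE)
    R1 <- rand_geom(n)
    s <- sample(n)
    R2 <- R1[s, ] + matrix(rnorm(3 * n, sd = 0.03), n, 3)
    c1 <- conformation(z, R1)
    c2 <- conformation(z[s], R2)
    pa <- bipartite_match(c1, c2)
    A_G <- adjacency_matrix(c1); A_H <- adjacency_matrix(c2)
    expect_equal(pa$cost, exhaustive_min_cost(A_G, A_H, c1$z, c2$z),
                 tolerance = 1e-12)
  }
})

test_that("matching two perturbed benzene rings returns a ring automorphism", {
  A0 <- benzene_template_adjacency()
  benz <- build_geometry("benzene")
  ds <- sample_conformations(benz, 10, cartesian_noise = 0.02, seed = 11)
  for (k in 1:5) {
    pa <- bipartite_match(ds[[2 * k - 1]], ds[[2 * k]])
    expect_true(is_template_automorphism(A0, pa$tau))
  }
})

test_that("synchronization yields exactly transitive assignments", {
  set.seed(706)
  toy <- make_toy_pes("rotor_molecule")
  ds <- sample_conformations(toy, 10, cartesian_noise = 0.05,
                             torsion_sampling = rotor_torsion_spec(),
                             seed = 13)
  mg <- synchronize(match_dataset(ds))
  # look up synchronized tau for ordered pair (i, j)
  tau_of <- function(i, j) {
    if (i < j) {
      k <- which(mg$pairs$i == i & mg$pairs$j == j)
      mg$synchronized[[k]]
    } else {
      k <- which(mg$pairs$i == j & mg$pairs$j == i)
      perm_inverse(mg$synchronized[[k]])
    }
  }
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (length(unique(c(i, j, k))) < 3) next
    expect_identical(perm_compose(tau_of(j, k), tau_of(i, j)), tau_of(i, k))
  }
})

test_that("a transitivity-violating edge is replaced by the tree composition", {
  # triangle: edges (1,2) and (1,3) have cost 0 and consistent assignments;
  # edge (2,3) carries a violating assignment with cost 5
  n <- 4
  t12 <- c(2L, 3L, 4L, 1L)
  t13 <- c(3L, 4L, 1L, 2L)
  bad23 <- c(2L, 1L, 4L, 3L)               # violates t13 o inv(t12)
  mg <- structure(list(
    n = 3L,
    pairs = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                       cost = c(0, 0, 5)),
    taus = list(t12, t13, bad23),
    tree_edges = NULL, tau_to_ref = NULL, synchronized = NULL),
    class = "matching_graph")
  out <- synchronize(mg)
  # tree keeps the two cost-0 edges; the synchronized (2,3) assignment is the
  # composition along the path 2 -> 1 -> 3
  expected <- perm_compose(t13, perm_inverse(t12))
  expect_identical(out$synchronized[[3]], expected)
  expect_false(identical(out$synchronized[[3]], bad23))
  expect_identical(out$synchronized[[1]], t12)
  expect_identical(out$synchronized[[2]], t13)
})

test_that("extract_symmetries handles degenerate and asymmetric inputs", {
  set.seed(707)
  R <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0.3, 1.7, 0), c(2.2, 0.9, 1.3))
  cf1 <- conformation(rep(6L, 4), R)
  expect_warning(sy1 <- extract_symmetries(mol_dataset(list(cf1))), "single")
  expect_equal(length(sy1), 1L)
  # all pairwise distances distinct: only the identity survives
  confs <- lapply(1:10, function(i)
    conformation(rep(6L, 4), R + matrix(rnorm(12, sd = 0.02), 4, 3)))
  sy <- extract_symmetries(mol_dataset(confs, name = "asym"))
  expect_equal(length(sy), 1L)
  expect_identical(sy$perms[[1]], 1:4)
})

test_that("symmetry sets are deduplicated, identity-first and charge-safe", {
  benz <- build_geometry("benzene")
  ds <- sample_conformations(benz, 12, cartesian_noise = 0.05, seed = 21)
  sy <- extract_symmetries(ds)
  keys <- vapply(sy$perms, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(sy$perms[[1]], perm_identity(12))
  z <- dataset_z(ds)
  for (s in sy$perms) expect_identical(z[s], z)
  expect_gte(length(sy), 1L)
})

test_that("symmetry_set constructor dedupes and prepends the identity", {
  sy <- symmetry_set(list(c(2L, 1L, 3L), c(2L, 1L, 3L), c(1L, 2L, 3L)))
  expect_equal(length(sy), 2L)
  expect_identical(sy$perms[[1]], 1:3)
  sy2 <- symmetry_set(list(c(3L, 1L, 2L)))
  expect_equal(length(sy2), 2L)
  expect_identical(sy2$perms[[1]], 1:3)
})

test_that("canonicalize_dataset aligns relabeled copies of one geometry", {
  set.seed(708)
  base <- rand_geom(6)
  z <- c(6L, 6L, 1L, 1L, 1L, 1L)
  confs <- list(conformation(z, base))
  for (i in 2:8) {
    s <- c(sample(1:2), sample(3:6))       # charge-preserving relabeling
    confs[[i]] <- conformation(z[s], base[s, ] +
                               matrix(rnorm(18, sd = 0.01), 6, 3))
  }
  ds <- mol_dataset(confs, name = "relabeled")
  can <- canonicalize_dataset(ds)
  A1 <- adjacency_matrix(can[[1]])
  for (i in 2:8) {
    expect_lt(max(abs(adjacency_matrix(can[[i]]) - A1)), 0.1)
    expect_identical(can[[i]]$z, can[[1]]$z)
  }
})
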