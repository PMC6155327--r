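# small labeled training sets from the analytic toys
toy_training_set <- function(pes, n, seed, noise = 0.05, torsions = NULL) {
  sample_conformations(pes, n, cartesian_noise = noise,
                       torsion_sampling = torsions, seed = seed)
}

test_that("the assembled kernel system is symmetric and positive definite", {
  set.seed(1001)
  pes <- make_toy_pes("harmonic_dimer")
  for (rep in 1:5) {
    ds <- toy_training_set(pes, 6, seed = rep)
    syms <- identity_symmetry(2)
    sys <- assemble_system(ds, syms, kernel_params(0.05))
    expect_lt(max(abs(sys$K - t(sys$K))), 1e-9)
    lam <- 1e-10
    ev <- eigen(sys$K + diag(lam * mean(diag(sys$K)), nrow(sys$K)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(length(sys$y), 6 * 6)
    # y is the stacked force labels, atom-major per frame
    expect_equal(sys$y[1:6], as.vector(t(ds[[1]]$F)))
  }
})

test_that("solve_coefficients escalates jitter on rank-deficient systems", {
  # duplicate training rows make K exactly singular at tiny lam
  K <- matrix(1, 4, 4) + diag(1e-12, 4)
  y <- rep(2, 4)
  sol <- solve_coefficients(K, y, lam = 1e-10)
  expect_true(all(is.finite(sol$alphas)))
  expect_gt(sol$jitter, 0)
  expect_lt(max(abs((K + diag(sol$jitter, 4)) %*% sol$alphas - y)), 1e-6)
})

test_that("training interpolates force labels at the training points", {
  rotor <- make_toy_pes("rotor_molecule")
  ds <- toy_training_set(rotor, 12, seed = 31, noise = 0.04,
                         torsions = rotor_torsion_spec())
  syms <- identity_symmetry(6)
  model <- sgdml_train(ds, syms, sigma = 2, lam = 1e-12)
  for (i in c(1, 5, 12)) {
    err <- max(abs(predict_forces(model, ds[[i]]$R) - ds[[i]]$F))
    expect_lt(err, 1e-6)
  }
})

test_that("the energy offset is the mean residual and vanishes when consistent", {
  rotor <- make_toy_pes("rotor_molecule")
  ds <- toy_training_set(rotor, 10, seed = 32, noise = 0.03)
  model <- sgdml_train(ds, identity_symmetry(6), sigma = 2, lam = 1e-12)
  # refitting on the same training data reproduces the stored offset
  expect_equal(fit_energy_offset(model, ds), model$energy_offset,
               tolerance = 1e-9)
  # shifting all labels by a constant shifts the offset by that constant
  shifted <- mol_dataset(lapply(ds$conformations, function(cf)
    conformation(cf$z, cf$R, E = cf$E + 7.5, F = cf$F)), name = "shifted")
  expect_equal(fit_energy_offset(model, shifted), model$energy_offset + 7.5,
               tolerance = 1e-9)
})

test_that("contracted symmetric training equals explicit symmetrized-dataset training", {
  # 3-atom toy with the exact swap symmetry of atoms 1 and 2: training with
  # the contracted symmetric kernel on M points must equal plain training on
  # the M*S explicitly permuted dataset
  set.seed(1002)
  z <- c(1L, 1L, 8L)
  swap <- c(2L, 1L, 3L)
  base <- rbind(c(-0.8, 0, 0), c(0.8, 0, 0), c(0, 0.6, 0))
  k_spring <- 150; r0 <- 1.1
  eval_pes <- function(R) {
    # symmetric pair-spring potential (exactly swap-invariant)
    pairs <- rbind(c(1, 3), c(2, 3), c(1, 2))
    r00 <- c(r0, r0, 1.6)
    E <- 0; F <- matrix(0, 3, 3)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      dvec <- R[i, ] - R[j, ]
      r <- sqrt(sum(dvec^2))
      E <- E + 0.5 * k_spring * (r - r00[p])^2
      fpair <- -k_spring * (r - r00[p]) * dvec / r
      F[i, ] <- F[i, ] + fpair
      F[j, ] <- F[j, ] - fpair
    }
    list(E = E, F = F)
  }
  confs <- lapply(1:4, function(i) {
    R <- base + matrix(rnorm(9, sd = 0.08), 3, 3)
    lab <- eval_pes(R)
    conformation(z, R, E = lab$E, F = lab$F)
  })
  train <- mol_dataset(confs, name = "swap-toy")
  syms <- symmetry_set(list(1:3, swap))
  lam <- 1e-12
  sigma <- 0.9
  m_sym <- sgdml_train(train, syms, sigma = sigma, lam = lam)
  # explicit dataset: every frame in both atom orders, plain kernel
  expl <- list()
  for (cf in train$conformations) {
    expl <- c(expl, list(cf, apply_perm(cf, swap)))
  }
  m_expl <- sgdml_train(mol_dataset(expl, name = "swap-toy-explicit"),
                        identity_symmetry(3), sigma = sigma, lam = lam)
  set.seed(1003)
  for (rep in 1:4) {
    Rq <- base + matrix(rnorm(9, sd = 0.08), 3, 3)
    ps <- predict_energy_forces(m_sym, Rq)
    pe <- predict_energy_forces(m_expl, Rq)
    scale_F <- max(1, max(abs(pe$F)))
    expect_lt(max(abs(ps$F - pe$F)) / scale_F, 1e-8)
    expect_lt(abs(ps$E - pe$E) / max(1, abs(pe$E)), 1e-8)
  }
})

test_that("cross-validation is deterministic and selects the grid minimum", {
  rotor <- make_toy_pes("rotor_molecule")
  ds <- toy_training_set(rotor, 30, seed = 33, noise = 0.04,
                         torsions = rotor_torsion_spec())
  grid <- c(0.5, 2, 8)
  m1 <- cross_validate(ds, sigma_grid = grid, n_train = 15, n_valid = 10,
                       seed = 5)
  m2 <- cross_validate(ds, sigma_grid = grid, n_train = 15, n_valid = 10,
                       seed = 5)
  expect_identical(m1$sigma, m2$sigma)
  expect_identical(m1$alphas, m2$alphas)
  cv <- m1$provenance$cv
  expect_equal(nrow(cv), 3L)
  expect_equal(m1$provenance$validation_mae, min(cv$f_mae))
  expect_equal(m1$sigma, cv$sigma[which.min(cv$f_mae)])
  expect_error(cross_validate(ds, sigma_grid = numeric(0), n_train = 5,
                              n_valid = 5), "grid")
  expect_error(cross_validate(ds, sigma_grid = grid, n_train = 30,
                              n_valid = 10), "split|exceed")
})

test_that("default sigma grid brackets the median descriptor distance", {
  rotor <- make_toy_pes("rotor_molecule")
  ds <- toy_training_set(rotor, 10, seed = 34)
  grid <- default_sigma_grid(ds)
  expect_equal(length(grid), 10L)
  Ds <- sapply(ds$conformations, function(cf) descriptor(cf$R)$D)
  med <- median(dist(t(Ds)))
  expect_lt(min(grid), med)
  expect_gt(max(grid), med)
})

test_that("model save/load round trip reproduces predictions", {
  rotor <- make_toy_pes("rotor_molecule")
  ds <- toy_training_set(rotor, 8, seed = 35)
  model <- sgdml_train(ds, identity_symmetry(6), sigma = 2)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  Rq <- ds[[1]]$R + 0.01
  expect_equal(predict_energy_forces(back, Rq),
               predict_energy_forces(model, Rq), tolerance = 1e-12)
  saveRDS(list(format = "nope"), path)
  expect_error(load_model(path), "not an sgdml model")
})
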