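test_that("NVE dynamics of the harmonic dimer reproduces the analytic period", {
  pes <- make_toy_pes("harmonic_dimer")
  k <- pes$springs$k[1]
  r0 <- pes$springs$r0[1]
  masses <- atomic_masses(pes$z)
  mu <- prod(masses) / sum(masses)
  # kcal/mol/Angstrom/amu -> Angstrom/fs^2 (independent recomputation:
  # 4184 J/mol / 1e-10 m / (1e-3 kg/mol) scaled to fs^2)
  conv <- 4184 / 6.02214076e23 / (1e-10)^2 / (1.66053906660e-27) * (1e-15)^2
  period <- 2 * pi * sqrt(mu / (k * conv))
  R0 <- rbind(c(0, 0, 0), c(r0 + 0.05, 0, 0))
  cfg <- md_config(dt = 0.2, n_steps = 2000, ensemble = "nve", seed = 1)
  traj <- run_md(pes, R0, cfg, V0 = matrix(0, 2, 3))
  expect_null(traj$error)
  bond <- sapply(seq_len(dim(traj$R)[1]), function(f)
    sqrt(sum((traj$R[f, 1, ] - traj$R[f, 2, ])^2)))
  # measure the period from successive maxima of the bond length
  dev <- bond - r0
  peaks <- which(diff(sign(diff(dev))) == -2) + 1
  expect_gt(length(peaks), 4)
  measured <- mean(diff(peaks)) * traj$dt
  expect_lt(abs(measured - period) / period, 0.005)
})

test_that("NVE total energy drift is below 1e-4 relative over long runs", {
  rotor <- make_toy_pes("rotor_molecule")
  cfg <- md_config(dt = 0.2, n_steps = 4000, ensemble = "nve",
                   temperature = 300, seed = 2)
  traj <- run_md(rotor, rotor$template, cfg)
  E_tot <- traj$E_pot + traj$E_kin
  scale <- mean(abs(E_tot))
  expect_gt(scale, 0)
  # symplectic integrator: energy oscillates within an O(dt^2) band but has
  # no secular drift; compare the first and last 5% window means
  w <- length(E_tot) %/% 20
  drift <- abs(mean(utils::tail(E_tot, w)) - mean(utils::head(E_tot, w)))
  expect_lt(drift, 1e-4 * scale)
  # and the bounded oscillation itself stays small
  expect_lt(max(E_tot) - min(E_tot), 1e-2 * scale)
})

test_that("the Langevin thermostat equilibrates to the target temperature", {
  rotor <- make_toy_pes("rotor_molecule")
  target <- 300
  cfg <- md_config(dt = 0.2, n_steps = 100000, ensemble = "nvt",
                   temperature = target, friction = 5, seed = 3,
                   stride = 10)
  traj <- run_md(rotor, rotor$template, cfg)
  kB <- 1.987204259e-3                      # kcal/mol/K, independent constant
  burn <- seq_along(traj$E_kin) > length(traj$E_kin) / 4
  mean_kin <- mean(traj$E_kin[burn])
  expected <- 1.5 * length(rotor$z) * kB * target
  expect_lt(abs(mean_kin - expected) / expected, 0.05)
})

test_that("trajectories honor stride and record shapes consistently", {
  pes <- make_toy_pes("harmonic_dimer")
  cfg <- md_config(dt = 0.2, n_steps = 10, stride = 5, seed = 4)
  traj <- run_md(pes, rbind(c(0, 0, 0), c(1.25, 0, 0)), cfg)
  expect_equal(dim(traj$R), c(3L, 2L, 3L))
  expect_equal(dim(traj$V), c(3L, 2L, 3L))
  expect_equal(length(traj$E_pot), 3L)
  expect_equal(traj$dt, 1.0)               # 0.2 fs * stride 5
})

test_that("a failing force provider truncates the trajectory with an error flag", {
  boom <- structure(list(z = c(1L, 1L)), class = "boom")
  calls <- new.env(); calls$n <- 0
  registerS3method("forcefield_eval", "boom", function(ff, R) {
    calls$n <- calls$n + 1
    if (calls$n > 5) stop("force blew up")
    list(E = 0, F = matrix(0, 2, 3))
  }, envir = asNamespace("sgdml"))
  cfg <- md_config(dt = 0.2, n_steps = 100, seed = 5)
  traj <- run_md(boom, rbind(c(0, 0, 0), c(1, 0, 0)), cfg, z = c(1L, 1L))
  expect_false(is.null(traj$error))
  expect_match(traj$error, "blew up")
  expect_lt(dim(traj$R)[1], 101L)
})

test_that("joint dihedral histogram is a probability map with correct binning", {
  # hand-built trajectory: 4-atom chain with prescribed torsions
  base <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.4, 1.5, 1.0))
  angles <- c(-150, -30, 45, 45, 120)
  frames <- lapply(angles, function(a) set_torsion(base, 1:4, 4L, a))
  Rarr <- array(0, c(5, 4, 3))
  for (f in 1:5) Rarr[f, , ] <- frames[[f]]
  traj <- structure(list(R = Rarr, dt = 1, masses = rep(1, 4)),
                    class = "trajectory")
  hist2 <- joint_dihedral_histogram(traj, 1:4, 1:4, bins = 36)
  expect_equal(sum(hist2$prob), 1, tolerance = 1e-12)
  # 45 degrees falls in bin ceiling((45+180)/10) = 23; two of five frames
  expect_equal(hist2$prob[23, 23], 2 / 5, tolerance = 1e-12)
})

test_that("minima occupations partition angle series exactly", {
  angles <- c(-170, -90, -30, 10, 100, 170)
  occ <- minima_occupations(angles, boundaries = c(-180, 0, 180))
  expect_equal(occ, c(0.5, 0.5))
  occ3 <- minima_occupations(angles, boundaries = c(-180, -60, 60, 180))
  expect_equal(occ3, c(2, 2, 2) / 6)
  expect_equal(sum(occ3), 1)
  expect_error(minima_occupations(angles, boundaries = c(-90, 90)),
               "boundaries")
  expect_error(minima_occupations(angles, boundaries = c(-180, 0, 0, 180)),
               "boundaries")
})

test_that("the VACF spectrum peaks at the analytic harmonic frequency", {
  pes <- make_toy_pes("harmonic_dimer")
  k <- pes$springs$k[1]; r0 <- pes$springs$r0[1]
  masses <- atomic_masses(pes$z)
  mu <- prod(masses) / sum(masses)
  conv <- 4184 / 6.02214076e23 / (1e-10)^2 / (1.66053906660e-27) * (1e-15)^2
  nu_cm1 <- sqrt(k * conv / mu) / (2 * pi) * 1e15 / 2.99792458e10
  R0 <- rbind(c(0, 0, 0), c(r0 + 0.05, 0, 0))
  cfg <- md_config(dt = 0.2, n_steps = 4096, ensemble = "nve", seed = 6)
  traj <- run_md(pes, R0, cfg, V0 = matrix(0, 2, 3))
  spec <- vacf_spectrum(traj, max_lag = 1000)
  expect_true(all(spec$power >= 0))
  expect_equal(max(spec$power), 1)
  peak <- spec$frequency[which.max(spec$power)]
  bin <- diff(spec$frequency[1:2])
  expect_lt(abs(peak - nu_cm1), bin + 1e-9)
  expect_error(vacf_spectrum(traj, max_lag = 5000), "too short")
})
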