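# Classical molecular dynamics with a trained model (or an analytic toy
# potential) and the observables used to characterize the dynamics:
# dihedral-angle distributions, conformer-basin occupations, and vibrational
# spectra from the velocity-velocity autocorrelation function.
#
# Internal MD units: Angstrom, femtosecond, amu, kcal/mol. The single
# conversion constant (.kcal_accel) turns kcal/mol/Angstrom/amu into
# Angstrom/fs^2; it is exercised by the harmonic-period oracle in the tests.

#' Evaluate a force field
#'
#' Generic over the force providers the MD engine accepts: trained
#' `sgdml_model`s and analytic `toy_pes` potentials.
#'
#' @param ff Force provider.
#' @param R N x 3 coordinates (Angstrom).
#' @return List with scalar `E` (kcal/mol) and N x 3 `F`
#'   (kcal/mol/Angstrom).
#' @export
forcefield_eval <- function(ff, R) UseMethod("forcefield_eval")

#' @export
forcefield_eval.sgdml_model <- function(ff, R) predict_energy_forces(ff, R)

#' @export
forcefield_eval.toy_pes <- function(ff, R) .toy_eval(ff, as.matrix(R))

#' MD configuration
#'
#' @param dt Integration timestep (fs); 0.2 fs is small enough to keep the
#'   total energy of stiff molecular modes conserved.
#' @param n_steps Number of integration steps.
#' @param ensemble `"nve"` (microcanonical, velocity Verlet) or `"nvt"`
#'   (Langevin thermostat).
#' @param temperature Target temperature in K (initial velocities; NVT bath).
#' @param friction Langevin friction in ps^-1 (NVT only).
#' @param seed Seed for initial velocities and the thermostat noise.
#' @param masses Per-atom masses in amu, or `NULL` to infer from the nuclear
#'   charges.
#' @param stride Keep every `stride`-th frame in the trajectory.
#' @return An `md_config` list.
#' @export
md_config <- function(dt = 0.2, n_steps = 1000L, ensemble = c("nve", "nvt"),
                      temperature = 300, friction = 1, seed = 0L,
                      masses = NULL, stride = 1L) {
  ensemble <- match.arg(ensemble)
  if (dt <= 0) stop("argument error: dt must be > 0")
  if (temperature <= 0) stop("argument error: temperature must be > 0")
  if (ensemble == "nvt" && friction <= 0) stop("argument error: friction must be > 0")
  structure(list(dt = dt, n_steps = as.integer(n_steps), ensemble = ensemble,
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed), masses = masses,
                 stride = as.integer(stride)),
            class = "md_config")
}

# Maxwell-Boltzmann velocities at temperature T with center-of-mass motion
# removed (called inside a seeded context)
.mb_velocities <- function(masses, temperature) {
  n <- length(masses)
  sd_v <- sqrt(.kB * temperature * .kcal_accel / masses)
  V <- matrix(stats::rnorm(3L * n), n, 3L) * sd_v
  vcom <- colSums(V * masses) / sum(masses)
  sweep(V, 2L, vcom)
}

.kinetic_energy <- function(V, masses) {
  0.5 * sum(masses * rowSums(V^2)) / .kcal_accel
}

#' Run classical molecular dynamics
#'
#' Velocity-Verlet integration; the NVT ensemble adds a Langevin thermostat
#' (exact Ornstein-Uhlenbeck velocity update after each step). Initial
#' velocities are Maxwell-Boltzmann at the target temperature with
#' center-of-mass motion removed, unless `V0` is supplied.
#'
#' @param ff Force provider (`sgdml_model` or `toy_pes`).
#' @param R0 N x 3 initial coordinates.
#' @param config An [md_config()].
#' @param V0 Optional N x 3 initial velocities (Angstrom/fs).
#' @param z Nuclear charges for mass lookup when `config$masses` is `NULL`
#'   and `ff` is not a model carrying them.
#' @return A `trajectory`: list with arrays `R`, `V` (frames x N x 3),
#'   vectors `E_pot`, `E_kin`, the sampling interval `dt` (fs), `masses`,
#'   `z`, and an `error` flag (non-`NULL` if a force evaluation failed and
#'   the trajectory was truncated).
#' @export
run_md <- function(ff, R0, config, V0 = NULL, z = NULL) {
  stopifnot(inherits(config, "md_config"))
  R <- as.matrix(R0)
  n <- nrow(R)
  if (is.null(z)) {
    z <- if (inherits(ff, "sgdml_model")) ff$z
         else if (inherits(ff, "toy_pes")) ff$z
         else stop("supply z for mass lookup")
  }
  masses <- if (!is.null(config$masses)) config$masses else atomic_masses(z)
  if (length(masses) != n) stop("masses/atom count mismatch")
  dt <- config$dt
  n_keep <- config$n_steps %/% config$stride + 1L
  Rtr <- array(NA_real_, c(n_keep, n, 3L))
  Vtr <- array(NA_real_, c(n_keep, n, 3L))
  E_pot <- numeric(n_keep); E_kin <- numeric(n_keep)
  err_flag <- NULL
  with_seed(config$seed, {
    V <- if (is.null(V0)) .mb_velocities(masses, config$temperature)
         else as.matrix(V0)
    ef <- forcefield_eval(ff, R)
    A <- ef$F / masses * .kcal_accel
    if (config$ensemble == "nvt") {
      gamma_fs <- config$friction * 1e-3               # ps^-1 -> fs^-1
      c1 <- exp(-gamma_fs * dt)
      c2 <- sqrt((1 - c1^2) * .kB * config$temperature * .kcal_accel / masses)
    }
    keep <- 1L
    Rtr[keep, , ] <- R; Vtr[keep, , ] <- V
    E_pot[keep] <- ef$E; E_kin[keep] <- .kinetic_energy(V, masses)
    for (step in seq_len(config$n_steps)) {
      V <- V + 0.5 * dt * A
      R <- R + dt * V
      ef <- tryCatch(forcefield_eval(ff, R), error = function(e) e)
      if (inherits(ef, "error")) {
        err_flag <- conditionMessage(ef)
        break
      }
      A <- ef$F / masses * .kcal_accel
      V <- V + 0.5 * dt * A
      if (config$ensemble == "nvt") {
        V <- c1 * V + matrix(stats::rnorm(3L * n), n, 3L) * c2
      }
      if (step %% config$stride == 0L) {
        keep <- keep + 1L
        Rtr[keep, , ] <- R; Vtr[keep, , ] <- V
        E_pot[keep] <- ef$E; E_kin[keep] <- .kinetic_energy(V, masses)
      }
    }
    if (!is.null(err_flag) && keep < n_keep) {
      Rtr <- Rtr[seq_len(keep), , , drop = FALSE]
      Vtr <- Vtr[seq_len(keep), , , drop = FALSE]
      E_pot <- E_pot[seq_len(keep)]; E_kin <- E_kin[seq_len(keep)]
    }
  })
  structure(list(R = Rtr, V = Vtr, E_pot = E_pot, E_kin = E_kin,
                 dt = dt * config$stride, masses = masses, z = z,
                 ensemble = config$ensemble, error = err_flag),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, dt = %.3g fs (%s)%s>\n",
              dim(x$R)[1L], dim(x$R)[2L], x$dt, x$ensemble,
              if (!is.null(x$error)) " [truncated by force error]" else ""))
  invisible(x)
}

# dihedral angle time series of a trajectory
.traj_angles <- function(traj, idx) {
  vapply(seq_len(dim(traj$R)[1L]),
         function(f) dihedral_angle(traj$R[f, , ], idx), numeric(1))
}

#' Joint probability map of two dihedral angles
#'
#' Normalized 2-D histogram of two torsion-angle time series over
#' (-180, 180]^2; the bin masses sum to one.
#'
#' @param traj A `trajectory`.
#' @param idx_a,idx_b Two dihedral specs (4 atom indices each).
#' @param bins Number of bins per axis (default 36).
#' @return List with `prob` (bins x bins), and bin edges `edges_a`,
#'   `edges_b`.
#' @export
joint_dihedral_histogram <- function(traj, idx_a, idx_b, bins = 36L) {
  n_frames <- dim(traj$R)[1L]
  if (n_frames < 1L) stop("argument error: empty trajectory")
  ang_a <- .traj_angles(traj, idx_a)
  ang_b <- .traj_angles(traj, idx_b)
  edges <- seq(-180, 180, length.out = bins + 1L)
  cut_ab <- function(a) pmin(pmax(ceiling((a + 180) / 360 * bins), 1L), bins)
  H <- matrix(0, bins, bins)
  ia <- cut_ab(ang_a); ib <- cut_ab(ang_b)
  for (f in seq_len(n_frames)) H[ia[f], ib[f]] <- H[ia[f], ib[f]] + 1
  list(prob = H / n_frames, edges_a = edges, edges_b = edges)
}

#' Occupation probabilities of torsional basins
#'
#' Fraction of frames whose dihedral angle falls into each basin of an
#' angular partition of (-180, 180].
#'
#' @param traj A `trajectory`, or directly a numeric vector of angles in
#'   degrees.
#' @param idx Dihedral spec (ignored when `traj` is an angle vector).
#' @param boundaries Increasing vector of basin edges starting at -180 and
#'   ending at 180 (basin b is (boundaries[b], boundaries[b+1]]).
#' @return Numeric vector of basin probabilities (sums to 1).
#' @export
minima_occupations <- function(traj, idx = NULL, boundaries) {
  ang <- if (is.numeric(traj)) traj else .traj_angles(traj, idx)
  if (is.unsorted(boundaries, strictly = TRUE) ||
      abs(boundaries[1L] + 180) > 1e-9 ||
      abs(boundaries[length(boundaries)] - 180) > 1e-9) {
    stop("argument error: boundaries must increase strictly from -180 to 180")
  }
  ang[ang <= -180] <- ang[ang <= -180] + 360
  b <- cut(ang, breaks = boundaries, labels = FALSE, include.lowest = TRUE)
  counts <- tabulate(b, nbins = length(boundaries) - 1L)
  counts / length(ang)
}

#' Vibrational spectrum from the velocity autocorrelation function
#'
#' Mass-weighted velocity-velocity autocorrelation averaged over atoms and
#' Cartesian components (computed with FFTs), apodized with a window over
#' lags 0..max_lag, cosine-transformed via an even extension, and normalized
#' to unit maximum. The frequency axis is in wavenumbers (cm^-1).
#'
#' @param traj A `trajectory` with uniform time spacing.
#' @param window Apodization: `"hann"` (default) or `"rect"`.
#' @param max_lag Maximum autocorrelation lag in frames (default half the
#'   trajectory length).
#' @return A `spectrum_vacf`: list with `frequency` (cm^-1, ascending from
#'   0), `power` (>= 0, unit maximum), and the lag-domain `vacf`.
#' @export
vacf_spectrum <- function(traj, window = c("hann", "rect"), max_lag = NULL) {
  window <- match.arg(window)
  nf <- dim(traj$R)[1L]
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  max_lag <- as.integer(max_lag)
  if (nf < 2L * max_lag || max_lag < 2L) {
    stop("argument error: trajectory too short for the requested max_lag")
  }
  n <- dim(traj$V)[2L]
  # unbiased autocorrelation of each atom/component series via FFT
  npad <- 2L^ceiling(log2(2L * nf))
  acf_total <- numeric(max_lag + 1L)
  for (a in seq_len(n)) {
    for (comp in 1:3) {
      x <- traj$V[, a, comp]
      X <- stats::fft(c(x, rep(0, npad - nf)))
      ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1L)] / npad
      acf_total <- acf_total + traj$masses[a] * ac / (nf - 0:max_lag)
    }
  }
  w <- if (window == "hann") {
    0.5 * (1 + cos(pi * (0:max_lag) / max_lag))
  } else rep(1, max_lag + 1L)
  cw <- acf_total * w
  # even extension -> real spectrum (cosine transform)
  ext <- c(cw, rev(cw[2:max_lag]))
  S <- Re(stats::fft(ext))
  nh <- max_lag + 1L                       # bins 0..Nyquist
  power <- pmax(S[seq_len(nh)], 0)
  freq <- (0:(nh - 1L)) / (length(ext) * traj$dt) * .per_fs_to_cm1
  if (max(power) > 0) power <- power / max(power)
  structure(list(frequency = freq, power = power, vacf = acf_total),
            class = "spectrum_vacf")
}
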