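# Closed-form training of the symmetrized gradient-domain model: assemble
# the 3NM x 3NM symmetric kernel system from force labels only, solve it by
# Cholesky factorization with escalating jitter, fit the energy integration
# constant, and select hyper-parameters by grid-search cross-validation.

#' Assemble the gradient-domain normal-equation system
#'
#' Builds the symmetric training kernel matrix from
#' [symmetric_hessian_train()] blocks and the stacked force-label vector
#' (atom-major component order per frame). Labels are forces only; no energy
#' penalty enters the system.
#'
#' @param train A [mol_dataset()] of canonicalized conformations carrying
#'   forces.
#' @param syms A `symmetry_set`.
#' @param params A [kernel_params()].
#' @return List with `K` (3NM x 3NM), `y` (length 3NM), and `descriptors`
#'   (list of per-frame [descriptor()]s).
#' @export
assemble_system <- function(train, syms, params) {
  stopifnot(inherits(train, "mol_dataset"), inherits(syms, "symmetry_set"),
            inherits(params, "kernel_params"))
  M <- length(train)
  n <- length(dataset_z(train))
  dim3n <- 3L * n
  if (any(vapply(train$conformations, function(cf) is.null(cf$F), logical(1)))) {
    stop("labeling error: all training conformations must carry forces")
  }
  descs <- lapply(train$conformations, function(cf) descriptor(cf$R))
  maps <- lapply(syms$perms, pair_perm_map)
  S <- length(maps)
  K <- matrix(0, dim3n * M, dim3n * M)
  for (i in seq_len(M)) {
    ri <- (i - 1L) * dim3n + seq_len(dim3n)
    for (j in i:M) {
      rj <- (j - 1L) * dim3n + seq_len(dim3n)
      core <- if (S == 1L) {
        .kdd(descs[[i]]$D, descs[[j]]$D, params$sigma)
      } else {
        .kdd_sym_train(descs[[i]]$D, descs[[j]]$D, maps, params$sigma)
      }
      block <- crossprod(descs[[i]]$J, core %*% descs[[j]]$J)
      K[ri, rj] <- block
      if (j > i) K[rj, ri] <- t(block)
    }
  }
  K <- (K + t(K)) / 2                      # exact numerical symmetry
  y <- unlist(lapply(train$conformations, function(cf) as.vector(t(cf$F))),
              use.names = FALSE)
  list(K = K, y = y, descriptors = descs)
}

#' Solve the regularized kernel system
#'
#' Solves `(K + jitter I) alpha = y` by Cholesky factorization, where
#' `jitter = lam * mean(diag(K))`. On factorization failure the jitter is
#' escalated tenfold up to a relative cap of 1e-4, after which a
#' conditioning error reporting the final jitter is raised.
#'
#' @param K Symmetric kernel matrix.
#' @param y Label vector.
#' @param lam Relative regularization weight (default 1e-10).
#' @return List with `alphas` (solution vector) and `jitter` (absolute
#'   jitter actually used).
#' @export
solve_coefficients <- function(K, y, lam = 1e-10) {
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  rel <- max(lam, 0)
  repeat {
    ch <- tryCatch(chol(K + diag(rel * scale, nrow(K))),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      alpha <- backsolve(ch, forwardsolve(t(ch), y))
      return(list(alphas = alpha, jitter = rel * scale))
    }
    rel <- max(rel, 1e-14) * 10
    if (rel > 1e-4) {
      stop(sprintf(
        "conditioning error: Cholesky failed up to relative jitter %.1e", rel))
    }
  }
}

#' Train a symmetrized gradient-domain force-field model
#'
#' Closed-form fit on force labels, followed by the energy integration
#' constant (mean energy residual) when energies are available.
#'
#' @param train A [mol_dataset()] with forces (and optionally energies),
#'   canonicalized so all frames share one atom ordering.
#' @param syms A `symmetry_set` (use [identity_symmetry()] for the plain,
#'   non-symmetric model).
#' @param sigma Kernel length scale.
#' @param lam Relative regularization (default 1e-10).
#' @return An object of class `sgdml_model`.
#' @export
sgdml_train <- function(train, syms, sigma, lam = 1e-10) {
  params <- kernel_params(sigma, lam)
  sys <- assemble_system(train, syms, params)
  sol <- solve_coefficients(sys$K, sys$y, lam)
  n <- length(dataset_z(train))
  M <- length(train)
  model <- structure(list(
    format = "sgdml-model-1",
    alphas = matrix(sol$alphas, nrow = M, ncol = 3L * n, byrow = TRUE),
    sigma = sigma, lam = lam, jitter = sol$jitter,
    syms = syms,
    train_descriptors = sys$descriptors,
    energy_offset = 0,
    z = dataset_z(train),
    provenance = list(train_name = train$name, M = M)),
    class = "sgdml_model")
  model$cache <- .predict_cache(model)
  if (!is.null(train[[1L]]$E)) {
    model$energy_offset <- fit_energy_offset(model, train)
  }
  model
}

#' @export
print.sgdml_model <- function(x, ...) {
  cat(sprintf(
    "<sgdml_model: M = %d training points, %d atoms, S = %d symmetries, sigma = %.4g, lam = %.1e>\n",
    nrow(x$alphas), length(x$z), length(x$syms$perms), x$sigma, x$lam))
  invisible(x)
}

#' Energy integration constant
#'
#' The gradient-domain model determines the energy only up to an additive
#' constant; it is fixed as the mean residual between the energy labels and
#' the unshifted model energies over the training set.
#'
#' @param model An `sgdml_model`.
#' @param train The training [mol_dataset()] with energies.
#' @return The scalar offset c (kcal/mol).
#' @export
fit_energy_offset <- function(model, train) {
  Es <- tryCatch(dataset_energies(train), error = function(e) NULL)
  if (is.null(Es)) {
    warning("no energies in training set: energy offset left at 0")
    return(0)
  }
  m0 <- model
  m0$energy_offset <- 0
  Ehat <- vapply(train$conformations,
                 function(cf) predict_energy(m0, cf$R), numeric(1))
  mean(Es - Ehat)
}

#' Default length-scale grid
#'
#' Ten log-spaced values spanning a factor of ~10 around the median pairwise
#' descriptor-space distance of the training set.
#'
#' @param train A [mol_dataset()].
#' @param n_grid Number of grid points (default 10).
#' @return Numeric vector of candidate sigmas.
#' @export
default_sigma_grid <- function(train, n_grid = 10L) {
  Ds <- vapply(train$conformations, function(cf) descriptor(cf$R)$D,
               numeric(length(descriptor(train[[1L]]$R)$D)))
  dm <- stats::dist(t(Ds))
  med <- stats::median(dm)
  if (!is.finite(med) || med <= 0) med <- 1
  exp(seq(log(med / 3), log(med * 3), length.out = n_grid))
}

#' Hyper-parameter selection by grid-search cross-validation
#'
#' Splits the dataset into dedicated training and validation parts, trains a
#' model per (sigma, lam) grid point, scores the per-component force MAE on
#' the validation part, and returns the best model. Ties are broken toward
#' smaller sigma, then smaller lam.
#'
#' @param dataset A [mol_dataset()] with force labels.
#' @param sigma_grid Numeric vector of length scales (default
#'   [default_sigma_grid()] of the training split).
#' @param lam_grid Numeric vector of relative regularization weights.
#' @param n_train,n_valid Split sizes.
#' @param seed Split seed.
#' @param syms `symmetry_set` used for every candidate (default identity
#'   only).
#' @return The selected `sgdml_model`, with `cv` (data frame of grid
#'   results) and `validation_mae` attached to its provenance.
#' @export
cross_validate <- function(dataset, sigma_grid = NULL, lam_grid = 1e-10,
                           n_train, n_valid, seed = 0L, syms = NULL) {
  sp <- split_dataset(dataset, n_train, n_valid, 0L, seed = seed)
  if (is.null(sp$train) || is.null(sp$valid)) {
    stop("argument error: empty training or validation split")
  }
  if (is.null(syms)) syms <- identity_symmetry(length(dataset_z(dataset)))
  if (is.null(sigma_grid)) sigma_grid <- default_sigma_grid(sp$train)
  if (length(sigma_grid) < 1L || length(lam_grid) < 1L) {
    stop("argument error: empty hyper-parameter grid")
  }
  sigma_grid <- sort(sigma_grid)
  lam_grid <- sort(lam_grid)
  results <- expand.grid(sigma = sigma_grid, lam = lam_grid,
                         KEEP.OUT.ATTRS = FALSE)
  results$f_mae <- NA_real_
  best <- NULL
  best_mae <- Inf
  for (r in seq_len(nrow(results))) {
    m <- sgdml_train(sp$train, syms, sigma = results$sigma[r],
                     lam = results$lam[r])
    err <- test_errors(m, sp$valid)
    results$f_mae[r] <- err$F_mae
    if (err$F_mae < best_mae) {            # strict: ties keep earlier (smaller) grid point
      best_mae <- err$F_mae
      best <- m
    }
  }
  best$provenance$cv <- results
  best$provenance$validation_mae <- best_mae
  best$provenance$seed <- seed
  best
}

#' Save a trained model
#' @param model An `sgdml_model`.
#' @param path Output path (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sgdml_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a trained model saved by [save_model()]
#' @param path Path to the model file.
#' @return An `sgdml_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sgdml-model-1")) {
    stop("not an sgdml model file: ", path)
  }
  class(obj) <- "sgdml_model"
  class(obj$syms) <- "symmetry_set"
  for (i in seq_along(obj$train_descriptors)) {
    class(obj$train_descriptors[[i]]) <- "descriptor"
  }
  obj
}
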