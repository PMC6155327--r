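# Evaluation of a trained model: forces from the symmetrized Hessian-kernel
# contraction and energies from the corresponding first-derivative kernel
# with the same coefficients, so the predicted force field is exactly the
# negative gradient of the predicted energy (a conservative field).

# cached per-model quantities: training descriptor matrix, contracted
# Jacobian-coefficient vectors, symmetry pair maps
.predict_cache <- function(model) {
  if (!is.null(model$cache)) return(model$cache)
  M <- nrow(model$alphas)
  d <- length(model$train_descriptors[[1L]]$D)
  Dm <- matrix(0, d, M)
  W <- matrix(0, d, M)
  for (i in seq_len(M)) {
    Dm[, i] <- model$train_descriptors[[i]]$D
    W[, i] <- model$train_descriptors[[i]]$J %*% model$alphas[i, ]
  }
  list(Dm = Dm, W = W,
       maps = lapply(model$syms$perms, pair_perm_map))
}

.check_query <- function(model, R) {
  R <- as.matrix(R)
  if (nrow(R) != length(model$z)) {
    stop("model/geometry error: atom count does not match the model")
  }
  R
}

# shared contraction: returns list(E_raw, t) where t is the descriptor-space
# force co-vector (F_hat = J_x^T t) and E_raw the unshifted energy
.predict_core <- function(model, desc_x) {
  cache <- .predict_cache(model)
  sigma <- model$sigma
  d <- length(desc_x$D)
  tvec <- numeric(d)
  E <- 0
  for (map in cache$maps) {
    Dq <- cache$Dm[map, , drop = FALSE]
    Wq <- cache$W[map, , drop = FALSE]
    U <- desc_x$D - Dq                     # column i: D_x - R_q D_i
    dd <- sqrt(colSums(U^2))
    gh <- .matern_g1h(dd, sigma)
    uw <- colSums(U * Wq)
    E <- E + sum(gh$g1 * uw)
    tvec <- tvec - (Wq %*% gh$g1 + U %*% (gh$h * uw))
  }
  list(E_raw = E, t = as.vector(tvec))
}

#' Predict forces for a geometry
#'
#' @param model An `sgdml_model`.
#' @param R N x 3 coordinate matrix with the model's atom ordering.
#' @return N x 3 force matrix (kcal/mol/Angstrom).
#' @export
predict_forces <- function(model, R) {
  stopifnot(inherits(model, "sgdml_model"))
  R <- .check_query(model, R)
  desc_x <- descriptor(R)
  core <- .predict_core(model, desc_x)
  f <- crossprod(desc_x$J, core$t)         # 3N, atom-major
  matrix(f, ncol = 3L, byrow = TRUE)
}

#' Predict the energy of a geometry
#'
#' Uses the first-derivative kernel contracted with the same coefficients as
#' the force predictor, plus the fitted integration constant, so that the
#' predicted forces are exactly the negative gradient of this energy.
#'
#' @inheritParams predict_forces
#' @return Scalar energy (kcal/mol).
#' @export
predict_energy <- function(model, R) {
  stopifnot(inherits(model, "sgdml_model"))
  R <- .check_query(model, R)
  core <- .predict_core(model, descriptor(R))
  core$E_raw + model$energy_offset
}

#' Energy and force prediction together
#'
#' One shared kernel contraction for both quantities; used by the MD engine.
#'
#' @inheritParams predict_forces
#' @return List with scalar `E` and N x 3 `F`.
#' @export
predict_energy_forces <- function(model, R) {
  stopifnot(inherits(model, "sgdml_model"))
  R <- .check_query(model, R)
  desc_x <- descriptor(R)
  core <- .predict_core(model, desc_x)
  list(E = core$E_raw + model$energy_offset,
       F = matrix(crossprod(desc_x$J, core$t), ncol = 3L, byrow = TRUE))
}

#' Test-set error report
#'
#' Force errors are computed over all 3N scalar components of all frames
#' (the common convention for these benchmarks); a per-atom force-vector
#' norm MAE is also reported, clearly labeled. Energy errors are per frame.
#'
#' @param model An `sgdml_model`.
#' @param test A [mol_dataset()] carrying the needed labels.
#' @return List with `F_mae`, `F_rmse`, `F_atom_norm_mae`
#'   (kcal/mol/Angstrom), and, when energies are present, `E_mae`, `E_rmse`
#'   (kcal/mol).
#' @export
test_errors <- function(model, test) {
  stopifnot(inherits(model, "sgdml_model"), inherits(test, "mol_dataset"))
  if (length(test) < 1L) stop("argument error: empty test set")
  has_F <- !is.null(test[[1L]]$F)
  has_E <- !is.null(test[[1L]]$E)
  if (!has_F && !has_E) stop("labeling error: test set carries no labels")
  dF <- c(); dFnorm <- c(); dE <- c()
  for (cf in test$conformations) {
    if (has_F || has_E) {
      pred <- predict_energy_forces(model, cf$R)
    }
    if (has_F) {
      resid <- pred$F - cf$F
      dF <- c(dF, as.vector(resid))
      dFnorm <- c(dFnorm, sqrt(rowSums(resid^2)))
    }
    if (has_E) dE <- c(dE, pred$E - cf$E)
  }
  out <- list()
  if (has_F) {
    out$F_mae <- mean(abs(dF))
    out$F_rmse <- sqrt(mean(dF^2))
    out$F_atom_norm_mae <- mean(dFnorm)
  }
  if (has_E) {
    out$E_mae <- mean(abs(dE))
    out$E_rmse <- sqrt(mean(dE^2))
  }
  out
}
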