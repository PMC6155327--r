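# Force-field kernel: Matern 5/2 in descriptor space, differentiated through
# the descriptor Jacobians to Cartesian coordinates, and its symmetrized
# variants. With the kernel a function of the descriptor difference only,
# the mixed second derivative with respect to the two geometry arguments
# factorizes exactly as J_a^T K_DD' J_b (no second-derivative-of-descriptor
# terms arise in cross blocks), which keeps every block closed form.
#
# Closed forms used throughout (s = sqrt(5)/sigma, d = |u|, u = D_a - D_b):
#   kappa(d)       = (1 + s d + s^2 d^2 / 3) exp(-s d)
#   g1(d) = kappa'(d)/d       = -(s^2/3) (1 + s d) exp(-s d)
#   h(d)  = (kappa'' - kappa'/d)/d^2 = (s^4/3) exp(-s d)
#   d^2 kappa / dD_a dD_b = -(g1 I + h u u^T)
# All three are smooth at d = 0.

#' Kernel hyper-parameters
#'
#' @param sigma Kernel length scale in descriptor units (> 0).
#' @param lam Regularization weight, relative to the mean diagonal of the
#'   training kernel matrix (>= 0).
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(sigma, lam = 1e-10) {
  if (!is.numeric(sigma) || sigma <= 0) stop("argument error: sigma must be > 0")
  if (!is.numeric(lam) || lam < 0) stop("argument error: lam must be >= 0")
  structure(list(sigma = sigma, lam = lam), class = "kernel_params")
}

# Matern 5/2 helper terms
.matern_g1h <- function(dd, sigma) {
  s <- sqrt(5) / sigma
  e <- exp(-s * dd)
  list(g1 = -(s^2 / 3) * (1 + s * dd) * e, h = (s^4 / 3) * e)
}

#' Matern 5/2 kernel value in descriptor space
#' @param D_a,D_b Descriptor vectors.
#' @param sigma Length scale.
#' @return Scalar kernel value.
#' @export
matern_kernel <- function(D_a, D_b, sigma) {
  s <- sqrt(5) / sigma
  dd <- sqrt(sum((D_a - D_b)^2))
  (1 + s * dd + s^2 * dd^2 / 3) * exp(-s * dd)
}

# descriptor-space cross Hessian d^2 kappa / dD_a dD_b
.kdd <- function(D_a, D_b, sigma) {
  u <- D_a - D_b
  dd <- sqrt(sum(u^2))
  gh <- .matern_g1h(dd, sigma)
  -(gh$g1 * diag(length(u)) + gh$h * tcrossprod(u))
}

#' Cartesian Hessian block of the kernel
#'
#' The 3N x 3N matrix of mixed second derivatives of the kernel with respect
#' to the Cartesian coordinates of its two arguments, chain-ruled through
#' both descriptor Jacobians. This is the force-force covariance block of
#' gradient-domain regression.
#'
#' @param desc_a,desc_b [descriptor()]s of the two geometries (same size).
#' @param params A [kernel_params()].
#' @return 3N x 3N matrix.
#' @export
kernel_hessian_block <- function(desc_a, desc_b, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (desc_a$n_atoms != desc_b$n_atoms) stop("molecule sizes differ")
  crossprod(desc_a$J, .kdd(desc_a$D, desc_b$D, params$sigma) %*% desc_b$J)
}

# descriptor-space core of the doubly symmetrized training block:
# (1/S) sum_{p,q} R_p^T Kdd(R_p D_a, R_q D_b) R_q, as an index-remapped
# accumulation (R_p, R_q are pair-index permutation matrices)
.kdd_sym_train <- function(D_a, D_b, maps, sigma) {
  d <- length(D_a)
  S <- length(maps)
  A <- matrix(0, d, d)
  for (p in seq_len(S)) {
    Dp <- D_a[maps[[p]]]
    for (q in seq_len(S)) {
      A[maps[[p]], maps[[q]]] <- A[maps[[p]], maps[[q]]] +
        .kdd(Dp, D_b[maps[[q]]], sigma)
    }
  }
  A / S
}

#' Symmetrized training kernel block
#'
#' The doubly symmetrized, 1/S-normalized Cartesian Hessian block: both
#' kernel arguments are averaged over the symmetry set, with rows and
#' columns permuted so the corresponding partial derivatives align. With
#' only the identity present this reduces exactly to
#' [kernel_hessian_block()].
#'
#' @param desc_a,desc_b [descriptor()]s (canonicalized geometries).
#' @param syms A `symmetry_set`.
#' @param params A [kernel_params()].
#' @return 3N x 3N matrix.
#' @export
symmetric_hessian_train <- function(desc_a, desc_b, syms, params) {
  stopifnot(inherits(syms, "symmetry_set"), length(syms$perms) >= 1L)
  if (length(syms$perms) == 1L) {
    return(kernel_hessian_block(desc_a, desc_b, params))
  }
  maps <- lapply(syms$perms, pair_perm_map)
  core <- .kdd_sym_train(desc_a$D, desc_b$D, maps, params$sigma)
  crossprod(desc_a$J, core %*% desc_b$J)
}

#' Symmetrized prediction kernel block
#'
#' Single-sided symmetrization used at evaluation time: the query argument
#' is not permuted and no 1/S normalization is applied.
#'
#' @param desc_query Descriptor of the query geometry.
#' @param desc_train Descriptor of the (canonicalized) training geometry.
#' @param syms A `symmetry_set`.
#' @param params A [kernel_params()].
#' @return 3N x 3N matrix.
#' @export
symmetric_hessian_predict <- function(desc_query, desc_train, syms, params) {
  stopifnot(inherits(syms, "symmetry_set"))
  d <- length(desc_query$D)
  A <- matrix(0, d, d)
  for (s in syms$perms) {
    map <- pair_perm_map(s)
    K <- .kdd(desc_query$D, desc_train$D[map], params$sigma)
    A[, map] <- A[, map] + K
  }
  crossprod(desc_query$J, A %*% desc_train$J)
}
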