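#' Mean relative error between a reference and a perturbed system matrix
#'
#' The error is the mean, over the nonzero entries of the reference matrix,
#' of `|Dnoisy_ij - D_ij| / D_ij`.  It is invariant to a simultaneous global
#' rescaling of both matrices.
#'
#' @param D_true Reference `system_matrix` (or sparse matrix).
#' @param D_noisy Perturbed matrix of the same shape.
#' @return Scalar mean relative error (a fraction).
#' @export
relative_error <- function(D_true, D_noisy) {
  A <- sysmat_entries(D_true); B <- sysmat_entries(D_noisy)
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  sa <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  if (nrow(sa) == 0L || all(sa$x == 0)) stop("reference matrix is all zero")
  keep <- sa$x != 0
  bij <- B[cbind(sa$i[keep], sa$j[keep])]
  mean(abs(bij - sa$x[keep]) / sa$x[keep])
}

# 3x3 box blur of an image vector on the grid, `passes` times; cheap
# smoothing used to draw spatially correlated random fields
blur_field <- function(v, nx, ny, passes = 3L) {
  M <- matrix(v, nrow = nx)  # x fastest
  for (p in seq_len(passes)) {
    up <- M[c(1, seq_len(nx - 1)), , drop = FALSE]
    dn <- M[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
    lf <- M[, c(1, seq_len(ny - 1)), drop = FALSE]
    rt <- M[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
    M <- (M + up + dn + lf + rt) / 5
  }
  as.numeric(M)
}

#' Perturb a system matrix at a requested mean relative error
#'
#' Emulates errors in the ray-dependent attenuation correction factors: a
#' smooth, mean-zero random error field `dmu` on the image grid (an error
#' in the attenuation image) perturbs every ray's factor through its line
#' integral, `f_i = exp(-s * (D dmu)_i)`, and row `i` of `D` is scaled by
#' `f_i`.  Errors of nearby rays are therefore strongly correlated -- a
#' wrong attenuation map distorts the sinogram coherently rather than
#' adding independent per-ray noise -- which is what makes reconstructions
#' with the wrong matrix systematically biased rather than merely noisier.
#' The sparsity pattern and entrywise nonnegativity of `D + dD` are
#' preserved.  The amplitude `s` is calibrated by bisection so that the
#' measured [relative_error()] of the perturbed matrix equals
#' `requested_error`.  Deterministic given `seed`.
#'
#' @param D A `system_matrix` (must carry its geometry).
#' @param requested_error Target mean relative error, a fraction `>= 0`
#'   (the simulated studies use 0-0.15).
#' @param seed Integer RNG seed.
#' @param smooth_passes Box-blur passes shaping the error-field correlation
#'   length (default 3).
#' @return A list of class `system_matrix_perturbation` with `delta_entries`
#'   (sparse dD), `requested_error`, `measured_error`, `row_factors`, `seed`.
#' @export
perturb_system_matrix <- function(D, requested_error, seed = 0L,
                                  smooth_passes = 3L) {
  stopifnot(inherits(D, "system_matrix"))
  E <- sysmat_entries(D)
  if (requested_error < 0) stop("requested_error must be nonnegative")
  m <- nrow(E)
  if (requested_error == 0) {
    return(structure(list(delta_entries = E * 0, requested_error = 0,
                          measured_error = 0, row_factors = rep(1, m),
                          seed = as.integer(seed)),
                     class = "system_matrix_perturbation"))
  }
  geom <- D$geometry
  set.seed(as.integer(seed))
  dmu <- stats::rnorm(geom$n)
  dmu <- blur_field(dmu, geom$grid_nx, geom$grid_ny, smooth_passes)
  dmu <- dmu - mean(dmu)
  g <- as.numeric(E %*% dmu)
  if (stats::sd(g) == 0) stop("degenerate error field")
  g <- g / stats::sd(g)
  nnz_row <- Matrix::rowSums(E != 0)
  wts <- nnz_row / sum(nnz_row)
  # measured error for row factors exp(-s g): nnz-weighted mean |f - 1|
  err_of <- function(s) sum(wts * abs(exp(-s * g) - 1))
  lo <- 0; hi <- 0.5
  while (err_of(hi) < requested_error && hi < 64) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (err_of(mid) < requested_error) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  f <- exp(-s * g)
  dE <- Matrix::Diagonal(m, f - 1) %*% E
  structure(list(delta_entries = methods::as(dE, "CsparseMatrix"),
                 requested_error = requested_error,
                 measured_error = err_of(s),
                 row_factors = f, seed = as.integer(seed)),
            class = "system_matrix_perturbation")
}

#' Apply a perturbation to a system matrix
#' @param D A `system_matrix`.
#' @param pert A `system_matrix_perturbation` from [perturb_system_matrix()].
#' @return A `system_matrix` with provenance `"perturbed"`.
#' @export
apply_perturbation <- function(D, pert) {
  stopifnot(inherits(D, "system_matrix"),
            inherits(pert, "system_matrix_perturbation"))
  as_system_matrix(D$entries + pert$delta_entries, D$geometry, "perturbed")
}

#' Norm-bounded uncertainty model
#'
#' Expresses system/measurement uncertainty as the perturbation set
#' `{Mf %*% Delta %*% [Ef, Eg] : ||Delta|| <= phi}` consumed by the robust
#' least-squares solver: `Mf` (m x p) is the left structure factor, `Ef`
#' (p x n) the structure through which uncertainty enters the system matrix,
#' `Eg` (length p) the structure entering the measurements, and `phi` bounds
#' the spectral norm of the contraction.  `error_level = 0` yields `Mf = 0`
#' (the accurate-model case): the robust solver then coincides with the
#' ordinary penalized WLS solver.
#'
#' Two built-in structures:
#' \describe{
#'   \item{`"isotropic"`}{`Mf = eta * I_m`, `Ef = I_n`, `eta = error_level *`
#'     max row sum of `D`.  A simple envelope: the spectral norm of any
#'     member is at most `error_level * ||D||_inf`.}
#'   \item{`"scaled_projector"`}{`Mf = I_m`, `Ef = error_level * D`.  Matches
#'     ray-multiplicative (attenuation-type) errors, for which the
#'     perturbation is proportional to `D` itself; the induced robust ridge
#'     `lambda * Ef' Ef` then scales with the projector instead of being an
#'     isotropic ridge.  Default for the reconstruction studies.}
#' }
#' `Eg = 0` in both (only system-side uncertainty is modeled), so the robust
#' correction modifies the effective penalty/weighting but adds no
#' measurement offset term.
#'
#' @param D A `system_matrix`.
#' @param error_level Assumed mean relative error of the system matrix
#'   (fraction `>= 0`).
#' @param structure `"isotropic"` or `"scaled_projector"`.
#' @param phi Contraction norm bound (default 1; the structures are
#'   calibrated to the typical perturbation magnitude at `phi = 1`).
#' @return An object of class `uncertainty_model` with fields `Mf`, `Ef`,
#'   `Eg`, `phi`, `error_level`, `structure` plus cached scalars used by the
#'   large-scale solver.
#' @export
make_norm_bounded_model <- function(D, error_level,
                                    structure = c("isotropic", "scaled_projector"),
                                    phi = 1) {
  structure_ <- match.arg(structure)
  if (error_level < 0) stop("error_level must be nonnegative")
  if (phi < 0) stop("phi must be nonnegative")
  E <- sysmat_entries(D)
  m <- nrow(E); n <- ncol(E)
  if (error_level == 0) {
    out <- list(Mf = Matrix::Diagonal(m, 0), Ef = Matrix::Diagonal(n, 0),
                Eg = rep(0, m), phi = 0, error_level = 0,
                structure = structure_, mf_scale = 0)
  } else if (structure_ == "isotropic") {
    eta <- error_level * max(Matrix::rowSums(E))
    out <- list(Mf = Matrix::Diagonal(m, eta), Ef = Matrix::Diagonal(n, 1),
                Eg = rep(0, m), phi = phi, error_level = error_level,
                structure = structure_, mf_scale = eta)
  } else {
    out <- list(Mf = Matrix::Diagonal(m, 1), Ef = error_level * E,
                Eg = rep(0, m), phi = phi, error_level = error_level,
                structure = structure_, mf_scale = 1)
  }
  class(out) <- "uncertainty_model"
  out
}

#' @export
print.uncertainty_model <- function(x, ...) {
  cat(sprintf("Norm-bounded uncertainty model (%s): error level %.3g, phi %.3g\n",
              x$structure, x$error_level, x$phi))
  invisible(x)
}

# TRUE when the model is the accurate-model (Mf = 0) case
is_certain <- function(U) {
  is.null(U) || U$error_level == 0 || U$phi == 0 || U$mf_scale == 0
}
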