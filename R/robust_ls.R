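#' Parameters of the robust least-squares solve
#'
#' Controls how the regularization scalar `lambda` of the min-max solution
#' is chosen.  `lambda` must satisfy `lambda >= lambda_lower`, the spectral
#' norm of `Mf' W Mf` (with the contraction bound `phi` folded into `Mf`),
#' for the corrected weighting matrix to be well defined.  The
#' `alpha_shortcut` mode sets `lambda = (1 + alpha) * lambda_lower`, the
#' recommended practical choice; `line_search` minimizes the scalar cost
#' `G(lambda)` over `[lambda_lower * (1 + eps), 100 * lambda_lower]` by
#' bounded scalar minimization.
#'
#' @param alpha Multiplier in `lambda = (1 + alpha) * lambda_lower`
#'   (default 0.5; must be `>= 0`).
#' @param lambda_mode `"alpha_shortcut"` (default) or `"line_search"`.
#' @param search_tolerance Tolerance of the scalar minimization.
#' @param lambda Optional explicit `lambda`; an error is raised if it is
#'   below `lambda_lower`.
#' @return A `robust_solve_params` list.
#' @export
robust_solve_params <- function(alpha = 0.5,
                                lambda_mode = c("alpha_shortcut", "line_search"),
                                search_tolerance = 1e-6, lambda = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  if (alpha < 0) stop("alpha must be nonnegative")
  structure(list(alpha = alpha, lambda_mode = lambda_mode,
                 search_tolerance = search_tolerance, lambda = lambda),
            class = "robust_solve_params")
}

as_dense_w <- function(W, m) {
  if (is.null(W)) diag(m)
  else if (is.vector(W) && length(W) == m) diag(W, m)
  else as.matrix(W)
}

#' Lower bound of the robust regularization scalar
#'
#' `lambda_lower = || (phi Mf)' W (phi Mf) ||_2`; any `lambda` at or above
#' this bound keeps the corrected weighting `W_hat` well defined.
#'
#' @param W Weighting matrix (matrix, or vector of diagonal weights).
#' @param Mf Left uncertainty structure factor (m x p).
#' @param phi Contraction norm bound (default 1).
#' @return Scalar lower bound.
#' @export
lambda_lower_bound <- function(W, Mf, phi = 1) {
  M <- phi * as.matrix(Mf)
  if (all(M == 0)) return(0)
  Wm <- as_dense_w(W, nrow(M))
  T_ <- crossprod(M, Wm %*% M)
  max(eigen((T_ + t(T_)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# corrected weighting W_hat(lambda) = W + W M (lambda I - M'WM)^+ M' W
w_hat_dense <- function(Wm, M, lambda) {
  if (all(M == 0)) return(Wm)
  T_ <- crossprod(M, Wm %*% M)
  S <- lambda * diag(nrow(T_)) - T_
  Sinv <- tryCatch({
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
    pos <- ev$values > max(ev$values, 1) * 1e-12
    if (!any(pos)) matrix(0, nrow(S), ncol(S))
    else ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  }, error = function(e) MASS::ginv(S))
  WM <- Wm %*% M
  Wm + WM %*% Sinv %*% t(WM)
}

# solve the corrected normal equations for a fixed lambda; returns x and the
# corrected matrices
robust_solve_fixed_lambda <- function(A, b, Wm, Qm, Ef, Eg, M, lambda) {
  What <- w_hat_dense(Wm, M, lambda)
  What <- (What + t(What)) / 2
  Qhat <- Qm + lambda * crossprod(Ef)
  H <- Qhat + crossprod(A, What %*% A)
  rhs <- as.numeric(crossprod(A, What %*% b)) +
    lambda * as.numeric(crossprod(Ef, Eg))
  x <- tryCatch(solve((H + t(H)) / 2, rhs),
                error = function(e)
                  stop("singular robust normal matrix: ", conditionMessage(e)))
  list(x = as.numeric(x), W_hat = What, Q_hat = Qhat)
}

# scalar cost G(lambda) minimized by the line search
robust_g_cost <- function(A, b, Wm, Qm, Ef, Eg, M, lambda) {
  sol <- robust_solve_fixed_lambda(A, b, Wm, Qm, Ef, Eg, M, lambda)
  x <- sol$x
  r <- as.numeric(A %*% x) - b
  e <- as.numeric(Ef %*% x) - Eg
  as.numeric(crossprod(x, Qm %*% x)) + lambda * sum(e * e) +
    as.numeric(crossprod(r, sol$W_hat %*% r))
}

#' Robust (min-max) regularized weighted least squares
#'
#' Solves `min_x max_{||Delta|| <= phi} ||x||^2_Q +
#' ||(A + Mf Delta Ef) x - (b + Mf Delta Eg)||^2_W` in closed form: with the
#' corrected matrices `Q_hat = Q + lambda Ef'Ef` and
#' `W_hat = W + W Mf (lambda I - Mf' W Mf)^+ Mf' W` (contraction bound
#' folded into `Mf`), the unique solution is
#' `x = (Q_hat + A' W_hat A)^{-1} (A' W_hat b + lambda Ef' Eg)`, where
#' `lambda >= lambda_lower = ||Mf' W Mf||` is chosen per `params`.  With
#' `Mf = 0` this reduces exactly to ordinary regularized WLS.
#'
#' @param A Design/system matrix (m x n, dense or sparse).
#' @param b Observation vector, length m.
#' @param W Weighting (matrix or diagonal vector); positive semidefinite.
#' @param Q Regularization matrix (n x n), positive semidefinite.
#' @param U An [make_norm_bounded_model()] `uncertainty_model` (or `NULL`
#'   for the certain case).
#' @param params A [robust_solve_params()].
#' @return List with `x`, `lambda`, `lambda_lower`, `Q_hat`, `W_hat`.
#' @export
robust_ls_solve <- function(A, b, W, Q, U = NULL,
                            params = robust_solve_params()) {
  A <- as.matrix(A); b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  Wm <- as_dense_w(W, m)
  Qm <- as.matrix(Q)
  if (is_certain(U)) {
    H <- Qm + crossprod(A, Wm %*% A)
    x <- solve((H + t(H)) / 2, as.numeric(crossprod(A, Wm %*% b)))
    return(list(x = as.numeric(x), lambda = 0, lambda_lower = 0,
                Q_hat = Qm, W_hat = Wm))
  }
  M <- U$phi * as.matrix(U$Mf)
  Ef <- as.matrix(U$Ef)
  Eg <- as.numeric(U$Eg)
  if (length(Eg) != nrow(Ef)) {
    if (length(Eg) == 1L) Eg <- rep(Eg, nrow(Ef))
    else stop("Eg length must match nrow(Ef)")
  }
  llow <- lambda_lower_bound(Wm, U$Mf, U$phi)
  lambda <- select_lambda(A, b, Wm, Qm, U, params)
  if (lambda < llow - 1e-12 * max(llow, 1))
    stop("lambda below its lower bound")
  sol <- robust_solve_fixed_lambda(A, b, Wm, Qm, Ef, Eg, M, lambda)
  list(x = sol$x, lambda = lambda, lambda_lower = llow,
       Q_hat = sol$Q_hat, W_hat = sol$W_hat)
}

#' Choose the robust regularization scalar lambda
#'
#' `alpha_shortcut`: `lambda = (1 + alpha) * lambda_lower`.  `line_search`:
#' bounded scalar minimization of the robust cost `G(lambda)` over
#' `[lambda_lower * (1 + 1e-6), 100 * lambda_lower]`, with the upper end
#' doubled while the cost still decreases there; ties break toward the
#' smaller `lambda`.
#'
#' @inheritParams robust_ls_solve
#' @return Scalar `lambda >= lambda_lower`.
#' @export
select_lambda <- function(A, b, W, Q, U, params = robust_solve_params()) {
  if (!is.null(params$lambda)) {
    llow <- lambda_lower_bound(W, U$Mf, U$phi)
    if (params$lambda < llow)
      stop(sprintf("requested lambda %.6g is below lambda_lower %.6g",
                   params$lambda, llow))
    return(params$lambda)
  }
  if (is_certain(U)) return(0)
  llow <- lambda_lower_bound(W, U$Mf, U$phi)
  if (params$lambda_mode == "alpha_shortcut" || llow == 0)
    return((1 + params$alpha) * llow)
  A <- as.matrix(A)
  Wm <- as_dense_w(W, nrow(A))
  Qm <- as.matrix(Q)
  M <- U$phi * as.matrix(U$Mf)
  Ef <- as.matrix(U$Ef)
  Eg <- as.numeric(U$Eg)
  if (length(Eg) == 1L) Eg <- rep(Eg, nrow(Ef))
  gof <- function(l) robust_g_cost(A, b, Wm, Qm, Ef, Eg, M, l)
  lo <- llow * (1 + 1e-6)
  hi <- llow * 100
  # extend the bracket while the cost is still decreasing at its upper end
  for (i in 1:14) {
    if (gof(hi) >= gof(hi / 2)) break
    hi <- hi * 2
  }
  opt <- stats::optimize(gof, interval = c(lo, hi),
                         tol = params$search_tolerance * max(llow, 1))
  # ties toward smaller lambda: accept the lower endpoint when as good
  if (gof(lo) <= opt$objective) lo else opt$minimum
}
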