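#' State-space model for the static reconstruction recursion
#'
#' In static imaging the activity is non-varying: the state transition is
#' the identity, `x(k+1) = x(k) + v(k)` with `v(k)` the model-uncertainty
#' noise (covariance `Qv = qv * I`), and the measurement equation is
#' `y(k) = D x(k) + e(k)` with noise covariance `R` (diagonal).  The
#' recursion re-presents the single measured sinogram at every step `k`;
#' `k` indexes update steps of a static image, not time frames.
#'
#' @param qv Scalar model-uncertainty variance (default `1e-3`).
#' @param R Diagonal measurement-noise variances: vector of length m, or
#'   `NULL` to use the plug-in Poisson variance `max(y, 1)` at fit time.
#' @param R0 Optional time-independent measurement-noise variance added to
#'   `R` (scalar, default 0).
#' @return A `state_space_model`.
#' @export
state_space_model <- function(qv = 1e-3, R = NULL, R0 = 0) {
  if (qv < 0) stop("qv must be nonnegative")
  if (!is.null(R) && any(R <= 0)) stop("R must be positive definite")
  if (R0 < 0) stop("R0 must be nonnegative")
  structure(list(qv = qv, R = R, R0 = R0, transition = "identity"),
            class = "state_space_model")
}

# robust fading-memory inflation factor of the prediction covariance:
# zero in the accurate-model case
robust_inflation <- function(U) {
  if (is_certain(U)) 0 else (U$phi * U$error_level)^2
}

# effective diagonal R for a given measurement vector
ssm_r_vector <- function(ssm, y) {
  r <- if (is.null(ssm$R)) pmax(as_sinogram_vector(y), 1) else ssm$R
  if (length(r) == 1L) r <- rep(r, length(as_sinogram_vector(y)))
  r + ssm$R0
}

# closed-form lambda_lower for diagonal Mf with diagonal W:
# || (phi mf)^2 W || = (phi*mf_scale)^2 * max(W)
lambda_lower_diag <- function(U, w) (U$phi * U$mf_scale)^2 * max(w)

# corrected diagonal weights W_hat for Mf = mf_scale * I (phi folded in):
# W_hat_i = w_i + w_i^2 c / (lambda - c w_i), c = (phi*mf_scale)^2; the
# pseudo-inverse convention drops terms with zero denominator.
w_hat_diag <- function(U, w, lambda) {
  cc <- (U$phi * U$mf_scale)^2
  if (cc == 0) return(w)
  den <- lambda - cc * w
  add <- ifelse(den > 1e-12 * max(lambda, 1), w^2 * cc / den, 0)
  w + add
}

# apply lambda * Ef'Ef to a vector for the built-in structures
ef_quad_mul <- function(U, E, v) {
  if (is_certain(U)) return(numeric(length(v)))
  if (U$structure == "isotropic") v
  else U$error_level^2 * as.numeric(Matrix::crossprod(E, E %*% v))
}

#' Initialize the UPWLS recursion
#'
#' The initial estimate is zero or the filtered-back-projection image (for
#' faster convergence); the initial covariance is the inverse of the
#' (ridge-augmented) smoothness penalty, `P(0) = Q^{-1}`.
#'
#' Two engines are kept behind the same interface: the exact dense
#' covariance recursion (small grids) and an information-form recursion
#' (large grids) that carries the information operator
#' `Y(k) = d_k * Q + c_k * (D' W_hat D + lambda Ef'Ef)` and solves each
#' correction with matrix-free conjugate gradient; the prediction step is a
#' scalar discount of the information operator, exact when `Qv = 0` and no
#' robust inflation is active.
#'
#' @param y0 The measured (corrected) sinogram.
#' @param D A `system_matrix`.
#' @param penalty A [smoothness_penalty()] (ridge-augmented internally; a
#'   singular penalty without the ridge raises an error).
#' @param ssm A [state_space_model()].
#' @param x0_mode `"zero"` or `"fbp"`.
#' @param mode `"auto"` (dense for `n <= 400`), `"dense"`, `"information"`.
#' @param rho Optional ridge for the penalty inversion (see
#'   [ridge_augment()]).
#' @return A `filter_state` with `x_hat`, covariance representation, step
#'   counter `k = 0` and cached problem terms.
#' @export
upwls_init <- function(y0, D, penalty, ssm = state_space_model(),
                       x0_mode = c("fbp", "zero"),
                       mode = c("auto", "dense", "information"),
                       rho = NULL) {
  x0_mode <- match.arg(x0_mode)
  mode <- match.arg(mode)
  E <- sysmat_entries(D)
  n <- ncol(E)
  if (mode == "auto") mode <- if (n <= 400L) "dense" else "information"
  Q0 <- ridge_augment(penalty, rho)
  y <- as_sinogram_vector(y0)
  x_hat <- if (x0_mode == "zero") numeric(n)
           else fbp_reconstruct(y, D$geometry, D)
  st <- list(mode = mode, x_hat = x_hat, k = 0L, Q0 = Q0,
             x0_mode = x0_mode, lambda = NULL, lambda_lower = NULL)
  if (mode == "dense") {
    Qd <- as.matrix(Q0)
    P0 <- tryCatch(chol2inv(chol(Qd)), error = function(e)
      stop("penalty Q is singular; supply a ridge (rho) so P(0) = Q^-1 exists"))
    st$P <- (P0 + t(P0)) / 2
  } else {
    st$d <- 1; st$cc <- 0  # Y = d*Q0 + cc*S
  }
  class(st) <- "filter_state"
  st
}

#' @export
print.filter_state <- function(x, ...) {
  cat(sprintf("UPWLS filter state (%s mode), step k = %d\n", x$mode, x$k))
  invisible(x)
}

#' UPWLS prediction (update) step
#'
#' Static transition: the mean is unchanged and the covariance is inflated
#' by the model-uncertainty covariance `Qv` plus a fading-memory robust
#' inflation `(phi * error_level)^2 * P` that widens the prior when the
#' system model is uncertain (`Mf != 0`); with an accurate model the step is
#' the classical `P- = P + Qv`.
#'
#' @param state A `filter_state`.
#' @param ssm A [state_space_model()].
#' @param U An `uncertainty_model` (or `NULL`).
#' @param params A [robust_solve_params()] (unused here; kept for interface
#'   symmetry).
#' @return The predicted `filter_state`.
#' @export
upwls_update <- function(state, ssm = state_space_model(), U = NULL,
                         params = robust_solve_params()) {
  gam <- robust_inflation(U)
  if (state$mode == "dense") {
    P <- (1 + gam) * state$P + diag(ssm$qv, nrow(state$P))
    P <- (P + t(P)) / 2
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      warning("predicted covariance lost positive definiteness; flooring")
      e <- eigen(P, symmetric = TRUE)
      vals <- pmax(e$values, max(e$values) * 1e-12)
      P <- e$vectors %*% (t(e$vectors) * vals)
      P <- (P + t(P)) / 2
    }
    state$P <- P
  } else {
    # scalar discount of the information operator; exact when qv = 0, gam = 0
    ybar <- if (is.null(state$meandiag)) 0 else state$meandiag
    state$dis <- 1 / (1 + gam + ssm$qv * ybar)
    state$d <- state$d * state$dis
    state$cc <- state$cc * state$dis
  }
  state
}

#' UPWLS correction step
#'
#' Robust measurement update: the regularized robust least-squares solve
#' with the prior `(x-, P-)` as the quadratic regularizer and
#' `(D, y, W = R^{-1}, U)` as the uncertain data.  With `Mf = 0` this is
#' exactly the information-form Kalman / penalized WLS update
#' `x = x- + P D' R^{-1} (y - D x-)`,
#' `P = ((P-)^{-1} + D' R^{-1} D)^{-1}`.
#'
#' @param state A predicted `filter_state`.
#' @param y_k The measurement (re-presented static sinogram).
#' @param D A `system_matrix`.
#' @param U An `uncertainty_model` (or `NULL`).
#' @param ssm A [state_space_model()].
#' @param params A [robust_solve_params()].
#' @return The corrected `filter_state`.
#' @export
upwls_correct <- function(state, y_k, D, U = NULL,
                          ssm = state_space_model(),
                          params = robust_solve_params()) {
  E <- sysmat_entries(D)
  y <- as_sinogram_vector(y_k)
  w <- 1 / ssm_r_vector(ssm, y)
  certain <- is_certain(U)

  # lambda: closed form for the built-in diagonal-Mf structures
  if (is.null(state$lambda)) {
    if (certain) {
      state$lambda <- 0; state$lambda_lower <- 0
    } else {
      llow <- lambda_lower_diag(U, w)
      state$lambda_lower <- llow
      state$lambda <-
        if (!is.null(params$lambda)) {
          if (params$lambda < llow) stop("lambda below its lower bound")
          params$lambda
        } else if (params$lambda_mode == "alpha_shortcut") {
          (1 + params$alpha) * llow
        } else {
          select_lambda(as.matrix(E), y, w, as.matrix(state$Q0), U, params)
        }
    }
  }
  lambda <- state$lambda
  what <- if (certain) w else w_hat_diag(U, w, lambda)
  r <- y - as.numeric(E %*% state$x_hat)

  if (state$mode == "dense") {
    Pinv <- chol2inv(chol(state$P))
    Pinv <- (Pinv + t(Pinv)) / 2
    Ed <- as.matrix(E)
    H <- Pinv + crossprod(Ed, Ed * what)
    rhs <- as.numeric(crossprod(Ed, what * r))
    if (!certain) {
      EftEf <- if (U$structure == "isotropic") diag(ncol(Ed))
               else U$error_level^2 * as.matrix(Matrix::crossprod(E))
      H <- H + lambda * EftEf
      # Eg = 0: shifted robust offset is -lambda Ef'Ef x-
      rhs <- rhs - lambda * as.numeric(EftEf %*% state$x_hat)
    }
    H <- (H + t(H)) / 2
    P <- chol2inv(chol(H))
    state$P <- (P + t(P)) / 2
    state$x_hat <- state$x_hat + as.numeric(P %*% rhs)
  } else {
    d <- state$d; cc_new <- state$cc + 1
    ymul <- function(v) {
      d * as.numeric(state$Q0 %*% v) +
        cc_new * (as.numeric(Matrix::crossprod(E, what * as.numeric(E %*% v))) +
                  lambda * ef_quad_mul(U, E, v))
    }
    rhs <- as.numeric(Matrix::crossprod(E, what * r)) -
      lambda * ef_quad_mul(U, E, state$x_hat)
    # cache diagonals of Q0 and S for the Jacobi preconditioner and the
    # prediction discount
    if (is.null(state$sdiag_vec)) {
      sdiag <- as.numeric(Matrix::crossprod(E^2, what))
      if (!certain) {
        sdiag <- sdiag + lambda *
          (if (U$structure == "isotropic") rep(1, length(sdiag))
           else U$error_level^2 * Matrix::colSums(E^2))
      }
      state$sdiag_vec <- sdiag
      state$qdiag_vec <- as.numeric(Matrix::diag(state$Q0))
    }
    ydiag <- d * state$qdiag_vec + cc_new * state$sdiag_vec
    sol <- cg_solve(ymul, rhs, tol = 1e-9, max_iter = 500L,
                    precond = ydiag)
    state$x_hat <- state$x_hat + sol$x
    state$cc <- cc_new
    state$meandiag <- mean(ydiag)
  }
  state$k <- state$k + 1L
  state
}

#' UPWLS reconstruction
#'
#' Full uncertainty-penalized weighted least-squares reconstruction: the
#' static state-space recursion repeats the prediction and robust correction
#' steps, re-presenting the same measured sinogram at each step, until two
#' consecutive normalized errors differ by at most `epsilon` or `max_iter`
#' steps have run.  Negative pixels are clipped to zero only at the final
#' output.
#'
#' @param y Corrected sinogram (vector or [sinogram()]).
#' @param D A `system_matrix` (the assumed model, possibly perturbed).
#' @param penalty A [smoothness_penalty()]; built from the geometry when
#'   `NULL`.
#' @param beta Scale of the smoothness prior: the recursion uses
#'   `beta * Q` (so `P(0) = (beta Q)^{-1}`).  Default `NULL` sets the prior
#'   pixel variance to the squared mean activity scale inferred from the
#'   counts (`beta = 1 / (xbar^2 * median diag Q)`).  Use a small value for
#'   low-noise data, where the prior mainly slows convergence.
#' @param ssm A [state_space_model()]; `R` defaults to `max(y, 1)`.
#' @param U An `uncertainty_model`; when `NULL`, built at `assumed_error`.
#' @param assumed_error Assumed system-matrix mean relative error used to
#'   build `U` when none is supplied (default 0: accurate model).
#' @param structure Uncertainty structure when `U` is built here (default
#'   `"isotropic"`; see [make_norm_bounded_model()]).
#' @param params A [robust_solve_params()].
#' @param x0_mode `"fbp"` (default) or `"zero"`.
#' @param epsilon Convergence constant on consecutive normalized errors
#'   (default `1e-4`).
#' @param max_iter Maximum recursion steps (default 200).
#' @param x_true Optional ground truth: the convergence errors are then the
#'   true normalized errors; otherwise the relative change of the iterate is
#'   used.
#' @param mode Engine selection, see [upwls_init()].
#' @return List with `x` (nonnegative estimate), `x_raw`, `trace`
#'   (iteration, normalized_error), `iterations`, `converged`, `lambda`,
#'   `lambda_lower`, `state`.
#' @export
upwls_reconstruct <- function(y, D, penalty = NULL, beta = NULL,
                              ssm = NULL, U = NULL, assumed_error = 0,
                              structure = "isotropic",
                              params = robust_solve_params(),
                              x0_mode = c("fbp", "zero"),
                              epsilon = 1e-4, max_iter = 200L,
                              x_true = NULL,
                              mode = c("auto", "dense", "information")) {
  x0_mode <- match.arg(x0_mode)
  mode <- match.arg(mode)
  geom <- if (inherits(D, "system_matrix")) D$geometry else NULL
  if (is.null(penalty)) {
    if (is.null(geom)) stop("penalty required when D carries no geometry")
    penalty <- smoothness_penalty(geom)
  }
  yvar <- if (inherits(y, "sinogram")) y$variance else NULL
  yv <- as_sinogram_vector(y)
  if (is.null(ssm)) ssm <- state_space_model()
  if (is.null(ssm$R) && !is.null(yvar)) ssm$R <- pmax(yvar, 1)
  if (is.null(U)) U <- make_norm_bounded_model(D, assumed_error,
                                               structure = structure)
  Qp <- if (inherits(penalty, "penalty_model")) penalty$Q else penalty
  if (is.null(beta)) {
    # prior pixel variance matched to the squared mean activity scale
    # inferred from the counts: P(0) ~ xbar^2 per pixel
    E <- sysmat_entries(D)
    xbar <- sum(pmax(yv, 0)) / max(sum(E), .Machine$double.eps)
    beta <- 1 / max(xbar^2 * stats::median(Matrix::diag(Qp)),
                    .Machine$double.eps)
  }
  penalty <- beta * Qp
  if (!is.null(x_true)) x_true <- as_activity_vector(x_true)
  state <- upwls_init(y, D, penalty, ssm, x0_mode = x0_mode, mode = mode)
  err_of <- function(xc, xp) {
    if (!is.null(x_true)) normalized_error(pmax(xc, 0), x_true)
    else sqrt(sum((xc - xp)^2)) / max(sqrt(sum(xp^2)), .Machine$double.eps)
  }
  e_prev <- if (!is.null(x_true)) normalized_error(pmax(state$x_hat, 0), x_true)
            else Inf
  trace <- data.frame(iteration = integer(0), normalized_error = numeric(0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x_old <- state$x_hat
    state <- upwls_update(state, ssm, U, params)
    state <- upwls_correct(state, yv, D, U, ssm, params)
    ek <- err_of(state$x_hat, x_old)
    trace <- rbind(trace, data.frame(iteration = it, normalized_error = ek))
    if (has_converged(ek, e_prev, epsilon)) {
      converged <- TRUE
      break
    }
    e_prev <- ek
  }
  if (!converged && max_iter > 0L && epsilon > 0)
    warning("UPWLS did not meet the convergence rule within max_iter; returning the last iterate")
  list(x = pmax(state$x_hat, 0), x_raw = state$x_hat, trace = trace,
       iterations = state$k, converged = converged,
       lambda = state$lambda, lambda_lower = state$lambda_lower,
       state = state)
}
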