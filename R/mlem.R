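#' MLEM reconstruction
#'
#' Standard maximum-likelihood expectation-maximization for Poisson emission
#' data, with the multiplicative update
#' `x <- x * D'(y / (D x)) / D'1`.  Negative input bins (corrected
#' sinograms) are clipped to zero before iterating, since MLEM requires
#' nonnegative data.  Voxels with zero sensitivity (`D'1 = 0`) are frozen at
#' their initial value with a warning.
#'
#' @param y Sinogram (vector or [sinogram()]); clipped to `>= 0`.
#' @param D A `system_matrix`.
#' @param n_iter Maximum number of iterations.
#' @param x0 Initial image, strictly positive (default: flat image matching
#'   the total counts).
#' @param x_true Optional ground truth; enables the normalized-error trace
#'   and the convergence rule `|e_k - e_{k-1}| <= epsilon`.
#' @param epsilon Convergence constant for consecutive normalized errors
#'   (used only when `x_true` is given; default 0, i.e. run `n_iter`).
#' @return List with `x` (estimate), `trace` (data.frame: iteration,
#'   loglik, normalized_error), `iterations`, `converged`.
#' @export
mlem_reconstruct <- function(y, D, n_iter = 100L, x0 = NULL, x_true = NULL,
                             epsilon = 0) {
  E <- sysmat_entries(D)
  y <- pmax(as_sinogram_vector(y), 0)
  if (length(y) != nrow(E)) stop("dimension mismatch")
  n <- ncol(E)
  sens <- as.numeric(Matrix::crossprod(E, rep(1, nrow(E))))
  dead <- sens <= 0
  if (any(dead))
    warning(sprintf("%d voxels have zero sensitivity; frozen at x0", sum(dead)))
  if (is.null(x0)) {
    x <- rep(max(sum(y), 1) / max(sum(sens), 1), n)
  } else {
    x <- as_activity_vector(x0)
    if (any(x <= 0)) stop("x0 must be strictly positive for MLEM")
  }
  if (!is.null(x_true)) x_true <- as_activity_vector(x_true)
  ll_tr <- numeric(n_iter); ek_tr <- numeric(n_iter)
  e_prev <- NA_real_
  converged <- FALSE
  it_done <- 0L
  sens_safe <- pmax(sens, .Machine$double.eps)
  for (it in seq_len(n_iter)) {
    proj <- as.numeric(E %*% x)
    ratio <- ifelse(proj > 0, y / proj, 0)
    corr <- as.numeric(Matrix::crossprod(E, ratio))
    xn <- x * corr / sens_safe
    xn[dead] <- x[dead]
    x <- xn
    proj <- as.numeric(E %*% x)
    ll_tr[it] <- sum(ifelse(y > 0 & proj > 0, y * log(proj), 0)) - sum(proj)
    ek_tr[it] <- if (is.null(x_true)) NA_real_ else normalized_error(x, x_true)
    it_done <- it
    if (!is.null(x_true) && !is.na(e_prev) && epsilon > 0 &&
        has_converged(ek_tr[it], e_prev, epsilon)) {
      converged <- TRUE
      break
    }
    e_prev <- ek_tr[it]
  }
  trace <- data.frame(iteration = seq_len(it_done),
                      loglik = ll_tr[seq_len(it_done)],
                      normalized_error = ek_tr[seq_len(it_done)])
  list(x = x, trace = trace, iterations = it_done, converged = converged)
}
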