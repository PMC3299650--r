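#' Quadratic smoothness penalty on the pixel grid
#'
#' Builds the sparse symmetric positive-semidefinite matrix `Q` of the
#' standard quadratic smoothing penalty `x' Q x = sum over 4-neighbor pairs
#' (x_j - x_k)^2` (the graph Laplacian of the lattice).  Constant images
#' incur zero penalty, so `Q` is singular; [ridge_augment()] adds the small
#' ridge needed when `Q` must be inverted (the prior covariance of the
#' state-space recursion).
#'
#' @param geom A [scan_geometry()].
#' @return A list of class `penalty_model` with sparse `Q`, the `geometry`
#'   and the `neighborhood` descriptor (`"4"`).
#' @export
smoothness_penalty <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  nx <- geom$grid_nx; ny <- geom$grid_ny
  idx <- function(ix, iy) iy * nx + ix + 1L  # 0-based grid coords
  ix <- rep(0:(nx - 1L), times = ny)
  iy <- rep(0:(ny - 1L), each = nx)
  # horizontal and vertical neighbor pairs
  hsel <- ix < nx - 1L
  vsel <- iy < ny - 1L
  pi_ <- c(idx(ix[hsel], iy[hsel]), idx(ix[vsel], iy[vsel]))
  pj_ <- c(idx(ix[hsel] + 1L, iy[hsel]), idx(ix[vsel], iy[vsel] + 1L))
  np <- length(pi_)
  # Q = B'B with B the pairwise difference operator
  B <- Matrix::sparseMatrix(i = rep(seq_len(np), 2L), j = c(pi_, pj_),
                            x = c(rep(1, np), rep(-1, np)),
                            dims = c(np, geom$n))
  Q <- methods::as(Matrix::crossprod(B), "CsparseMatrix")
  structure(list(Q = Q, geometry = geom, neighborhood = "4"),
            class = "penalty_model")
}

#' @export
print.penalty_model <- function(x, ...) {
  cat(sprintf("Quadratic smoothness penalty (%s-neighbor), %d x %d\n",
              x$neighborhood, nrow(x$Q), ncol(x$Q)))
  invisible(x)
}

#' Ridge-augment a singular smoothness penalty
#'
#' `Q + rho * I` with `rho = 1e-6 * trace(Q) / n` by default, making the
#' penalty invertible so it can serve as the initial information matrix of
#' the state-space recursion.
#'
#' @param penalty A `penalty_model` or sparse matrix.
#' @param rho Ridge size; default `1e-6 * trace(Q)/n`.
#' @return Sparse matrix `Q + rho I`.
#' @export
ridge_augment <- function(penalty, rho = NULL) {
  Q <- if (inherits(penalty, "penalty_model")) penalty$Q else penalty
  n <- nrow(Q)
  if (is.null(rho)) rho <- 1e-6 * sum(Matrix::diag(Q)) / n
  Q + Matrix::Diagonal(n, rho)
}

# matrix-free preconditioned conjugate gradient for SPD operators.
# ENVIRONMENT provides no matrix-free Krylov solver for R, so a compact PCG
# is kept here; `amul` maps a vector to A %*% v; `precond` is the diagonal
# of a Jacobi preconditioner (optional).
cg_solve <- function(amul, b, x0 = NULL, tol = 1e-10, max_iter = 500L,
                     precond = NULL) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - amul(x)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(list(x = numeric(length(b)), iters = 0L, relres = 0))
  minv <- if (is.null(precond)) NULL else 1 / pmax(precond, .Machine$double.eps)
  z <- if (is.null(minv)) r else minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- amul(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break  # loss of positive definiteness; return best iterate
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * b2) {
      return(list(x = x, iters = it, relres = sqrt(sum(r * r)) / b2))
    }
    z <- if (is.null(minv)) r else minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iters = max_iter, relres = sqrt(sum((b - amul(x))^2)) / b2)
}
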