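#' Fit a PET reconstruction
#'
#' The modelling front door: reconstructs an activity image from a
#' (corrected) sinogram with one of the three estimators — `"mlem"`
#' (maximum-likelihood EM), `"pwls"` (penalized weighted least squares by
#' conjugate gradient) or `"upwls"` (the robust min-max state-space
#' recursion) — and returns a classed fit with the usual methods
#' (`print`, `summary`, `coef`, `fitted`, `residuals`, `plot`).
#'
#' @param y Measured sinogram ([sinogram()] or vector, length m).
#' @param D A `system_matrix` (the assumed model; may be perturbed).
#' @param method `"mlem"`, `"pwls"` or `"upwls"`.
#' @param x_true Optional ground truth (enables error traces/summaries).
#' @param n_iter Iteration budget (defaults: 100 / 50 / 30 by method).
#' @param ... Further arguments passed to the method backend
#'   ([mlem_reconstruct()], [pwls_cg_reconstruct()],
#'   [upwls_reconstruct()]).
#' @return An object of class `pet_recon`.
#' @examples
#' g <- scan_geometry(16, 16, n_angles = 12, n_bins = 23)
#' D <- build_system_matrix(g)
#' ph <- shepp_logan_phantom(g)
#' y <- forward_project(D, ph)
#' fit <- pet_recon(y, D, method = "mlem", n_iter = 20, x_true = ph)
#' coef(fit)[1:5]
#' @export
pet_recon <- function(y, D, method = c("mlem", "pwls", "upwls"),
                      x_true = NULL, n_iter = NULL, ...) {
  method <- match.arg(method)
  if (is.null(n_iter))
    n_iter <- switch(method, mlem = 100L, pwls = 50L, upwls = 30L)
  res <- switch(method,
    mlem = mlem_reconstruct(y, D, n_iter = n_iter, x_true = x_true, ...),
    pwls = pwls_cg_reconstruct(y, D, n_iter = n_iter, x_true = x_true, ...),
    upwls = suppressWarnings(
      upwls_reconstruct(y, D, max_iter = n_iter, x_true = x_true, ...)))
  geom <- if (inherits(D, "system_matrix")) D$geometry else NULL
  out <- list(method = method, x = res$x, trace = res$trace,
              iterations = res$iterations, geometry = geom,
              y = as_sinogram_vector(y), D = D, x_true = x_true,
              backend = res)
  class(out) <- "pet_recon"
  out
}

#' @export
print.pet_recon <- function(x, ...) {
  cat(sprintf("PET reconstruction (%s), %d iterations\n",
              toupper(x$method), x$iterations))
  if (!is.null(x$geometry))
    cat(sprintf("  grid %d x %d, %d angles x %d bins\n",
                x$geometry$grid_nx, x$geometry$grid_ny,
                x$geometry$n_angles, x$geometry$n_bins))
  if (!is.null(x$x_true))
    cat(sprintf("  final normalized error: %.4f\n",
                normalized_error(x$x, x$x_true)))
  invisible(x)
}

#' @export
summary.pet_recon <- function(object, ...) {
  s <- list(method = object$method, iterations = object$iterations,
            total_activity = sum(object$x), max_activity = max(object$x),
            final_error = if (!is.null(object$x_true))
              normalized_error(object$x, object$x_true) else NA_real_,
            bias_std = if (!is.null(object$x_true))
              bias_std(object$x, object$x_true) else NULL)
  class(s) <- "summary.pet_recon"
  s
}

#' @export
print.summary.pet_recon <- function(x, ...) {
  cat(sprintf("PET reconstruction summary (%s)\n", toupper(x$method)))
  cat(sprintf("  iterations:      %d\n", x$iterations))
  cat(sprintf("  total activity:  %.4g\n", x$total_activity))
  cat(sprintf("  max activity:    %.4g\n", x$max_activity))
  if (!is.na(x$final_error)) {
    cat(sprintf("  normalized error: %.4f\n", x$final_error))
    cat(sprintf("  bias / std:       %.4f / %.4f\n",
                x$bias_std[["bias"]], x$bias_std[["std"]]))
  }
  invisible(x)
}

#' @export
coef.pet_recon <- function(object, ...) object$x

#' @export
fitted.pet_recon <- function(object, ...) forward_project(object$D, object$x)

#' @export
residuals.pet_recon <- function(object, ...) object$y - fitted(object)

#' @export
plot.pet_recon <- function(x, ...) {
  img <- matrix(x$x, nrow = x$geometry$grid_nx)  # x index fastest
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                  xlab = "x", ylab = "y", useRaster = TRUE,
                  main = sprintf("%s reconstruction", toupper(x$method)),
                  ...)
  invisible(x)
}
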