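#' Activity image container
#'
#' A nonnegative length-n vector of per-voxel radioactivity on a
#' [scan_geometry()] grid, stored row-major (x index fastest).
#'
#' @param values Numeric vector of length `geom$n`, all `>= 0`.
#' @param geom A [scan_geometry()].
#' @return An `activity_image`.
#' @export
activity_image <- function(values, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  values <- as.numeric(values)
  if (length(values) != geom$n) stop("values length must equal geom$n")
  if (any(!is.finite(values))) stop("activity values must be finite")
  if (any(values < 0)) stop("activity values must be nonnegative")
  structure(list(values = values, geometry = geom), class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf("Activity image %d x %d: total %.4g, max %.4g\n",
              x$geometry$grid_nx, x$geometry$grid_ny,
              sum(x$values), max(x$values)))
  invisible(x)
}

#' @rdname activity_image
#' @param x An `activity_image`.
#' @param ... Unused.
#' @export
as.matrix.activity_image <- function(x, ...) {
  matrix(x$values, nrow = x$geometry$grid_ny,
         ncol = x$geometry$grid_nx, byrow = TRUE)
}

as_activity_vector <- function(x) {
  if (inherits(x, "activity_image")) x$values else as.numeric(x)
}

#' Sinogram container
#'
#' A length-m vector of per-bin counts (angle-major ordering).  Prompt and
#' delayed kinds hold nonnegative integer counts; the corrected kind (after
#' randoms/scatter subtraction) may contain negative bins; the noiseless
#' kind holds expected values.
#'
#' @param values Numeric vector of length `geom$m`.
#' @param geom A [scan_geometry()].
#' @param kind One of `"prompt"`, `"delayed"`, `"corrected"`, `"noiseless"`.
#' @param variance Optional per-bin variance estimate (used by the
#'   least-squares reconstructors as plug-in weights; attached by
#'   [correct_sinogram()]).
#' @return A `sinogram`.
#' @export
sinogram <- function(values, geom,
                     kind = c("noiseless", "prompt", "delayed", "corrected"),
                     variance = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != geom$m) stop("values length must equal geom$m")
  if (kind %in% c("prompt", "delayed")) {
    if (any(values < 0) || any(abs(values - round(values)) > 1e-8))
      stop(sprintf("%s sinogram must hold nonnegative integer counts", kind))
  }
  if (!is.null(variance) && length(variance) != geom$m)
    stop("variance length must equal geom$m")
  structure(list(values = values, geometry = geom, kind = kind,
                 variance = variance),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram (%s): %d angles x %d bins, total %.4g\n",
              x$kind, x$geometry$n_angles, x$geometry$n_bins, sum(x$values)))
  invisible(x)
}

as_sinogram_vector <- function(y) {
  if (inherits(y, "sinogram")) y$values else as.numeric(y)
}

sinogram_kind <- function(y) if (inherits(y, "sinogram")) y$kind else NA_character_
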