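#' Write / read an activity image
#'
#' Images travel in two plain formats: NIfTI (a single 2-D slice, via
#' RNifti) for downstream viewers, and whitespace-delimited text matrices
#' for small fixtures and tests.
#'
#' @param x An [activity_image()].
#' @param path Output file; `.nii`/`.nii.gz` selects NIfTI, anything else a
#'   text matrix.
#' @return `path`, invisibly.
#' @export
write_activity <- function(x, path) {
  stopifnot(inherits(x, "activity_image"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- matrix(x$values, nrow = x$geometry$grid_nx)  # x fastest
    RNifti::writeNifti(RNifti::asNifti(arr,
      pixdim = rep(x$geometry$pixel_size, 2)), path)
  } else {
    utils::write.table(as.matrix(x), path, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_activity
#' @param geom The [scan_geometry()] of the stored image.
#' @export
read_activity <- function(path, geom) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    activity_image(as.numeric(arr), geom)  # x-fastest layout round-trips
  } else {
    m <- as.matrix(utils::read.table(path))
    activity_image(as.numeric(t(m)), geom)
  }
}

#' Write / read a sinogram as CSV
#'
#' Columns `angle`, `bin`, `value` (1-based indices, angle-major order)
#' plus a header comment carrying the kind tag.
#'
#' @param y A [sinogram()].
#' @param path Output CSV path.
#' @return `path` invisibly / the [sinogram()].
#' @export
write_sinogram_csv <- function(y, path) {
  stopifnot(inherits(y, "sinogram"))
  g <- y$geometry
  df <- data.frame(angle = rep(seq_len(g$n_angles), each = g$n_bins),
                   bin = rep(seq_len(g$n_bins), times = g$n_angles),
                   value = y$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sinogram kind=%s n_angles=%d n_bins=%d",
                     y$kind, g$n_angles, g$n_bins), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram_csv
#' @param geom The [scan_geometry()].
#' @export
read_sinogram_csv <- function(path, geom) {
  hdr <- readLines(path, n = 1L)
  kind <- sub(".*kind=(\\w+).*", "\\1", hdr)
  df <- utils::read.csv(path, comment.char = "#")
  ord <- order(df$angle, df$bin)
  sinogram(df$value[ord], geom, kind = kind)
}

#' Scan container: a plain-text on-disk dataset
#'
#' A directory holding one complete synthetic scan: `meta.yaml` (geometry,
#' protocol, perturbation request/seed, activity-to-counts scale),
#' `phantom.txt` (text matrix), `D.mtx` and `deltaD.mtx` (MatrixMarket
#' sparse matrices) and per-realization `prompt_<r>.csv` /
#' `delayed_<r>.csv` sinograms.
#'
#' @param dir Container directory (created if needed).
#' @param phantom [activity_image()] ground truth.
#' @param D Exact `system_matrix`.
#' @param pert Optional `system_matrix_perturbation`.
#' @param proto The [scan_protocol()].
#' @param scans List of `simulate_scan()` results (one per realization).
#' @return `dir`, invisibly.
#' @export
write_scan_container <- function(dir, phantom, D, pert, proto, scans) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- D$geometry
  meta <- list(
    geometry = list(grid_nx = g$grid_nx, grid_ny = g$grid_ny,
                    pixel_size = g$pixel_size, n_angles = g$n_angles,
                    n_bins = g$n_bins, bin_width = g$bin_width,
                    image_order = "row-major (x fastest)",
                    sinogram_order = "angle-major"),
    protocol = list(total_counts = proto$total_counts,
                    random_fraction = proto$random_fraction,
                    scatter_fraction = proto$scatter_fraction,
                    n_realizations = proto$n_realizations,
                    seed = proto$seed),
    perturbation = if (is.null(pert)) NULL else
      list(requested_error = pert$requested_error,
           measured_error = pert$measured_error, seed = pert$seed),
    scale = if (length(scans)) scans[[1]]$scale else NA_real_)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  write_activity(phantom, file.path(dir, "phantom.txt"))
  Matrix::writeMM(D$entries, file.path(dir, "D.mtx"))
  if (!is.null(pert))
    Matrix::writeMM(pert$delta_entries, file.path(dir, "deltaD.mtx"))
  for (r in seq_along(scans)) {
    write_sinogram_csv(scans[[r]]$prompt,
                       file.path(dir, sprintf("prompt_%d.csv", r - 1L)))
    write_sinogram_csv(scans[[r]]$delayed,
                       file.path(dir, sprintf("delayed_%d.csv", r - 1L)))
  }
  invisible(dir)
}

#' @rdname write_scan_container
#' @export
read_scan_container <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  gm <- meta$geometry
  geom <- scan_geometry(gm$grid_nx, gm$grid_ny, gm$n_angles, gm$n_bins,
                        pixel_size = gm$pixel_size, bin_width = gm$bin_width)
  pr <- meta$protocol
  proto <- scan_protocol(pr$total_counts, pr$random_fraction,
                         pr$scatter_fraction, pr$n_realizations, pr$seed)
  D <- as_system_matrix(Matrix::readMM(file.path(dir, "D.mtx")), geom)
  delta_path <- file.path(dir, "deltaD.mtx")
  Dh <- if (file.exists(delta_path))
    as_system_matrix(D$entries +
                       methods::as(Matrix::readMM(delta_path), "CsparseMatrix"),
                     geom, "perturbed")
  else NULL
  phantom <- read_activity(file.path(dir, "phantom.txt"), geom)
  reals <- list()
  r <- 0L
  repeat {
    pf <- file.path(dir, sprintf("prompt_%d.csv", r))
    if (!file.exists(pf)) break
    reals[[r + 1L]] <- list(
      prompt = read_sinogram_csv(pf, geom),
      delayed = read_sinogram_csv(file.path(dir, sprintf("delayed_%d.csv", r)),
                                  geom))
    r <- r + 1L
  }
  list(meta = meta, geometry = geom, protocol = proto, phantom = phantom,
       D = D, D_perturbed = Dh, realizations = reals,
       scale = meta$scale)
}
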