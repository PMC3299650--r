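#' Build the intersection-length system matrix
#'
#' Traces one ray per (angle, bin) through the pixel grid and records the
#' length of the ray inside every pixel it crosses (the single-ray
#' approximation to the detection probability: longer intersection, larger
#' sensitivity).  Rows are sinogram bins in angle-major order, columns are
#' image pixels in row-major order; see [scan_geometry()].
#'
#' The tracer is a Siddon-style parametric sweep: the ray's crossings with
#' all pixel boundary lines are sorted, and each inter-crossing segment is
#' assigned to the pixel containing its midpoint.
#'
#' @param geom A [scan_geometry()].
#' @return An object of class `system_matrix`: a list with `entries` (a
#'   sparse `dgCMatrix`, m x n), `geometry`, and `provenance` (`"exact"`).
#' @examples
#' g <- scan_geometry(2, 2, n_angles = 1, n_bins = 2)
#' D <- build_system_matrix(g)
#' Matrix::rowSums(D$entries)  # each vertical ray crosses two unit pixels
#' @export
build_system_matrix <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (geom$n < 1L || geom$m < 1L) stop("zero-size geometry")
  px <- geom$pixel_size
  org <- grid_origin(geom)
  nx <- geom$grid_nx; ny <- geom$grid_ny
  xlines <- org[1] + (0:nx) * px
  ylines <- org[2] + (0:ny) * px
  xmax <- xlines[nx + 1L]; ymax <- ylines[ny + 1L]

  ri <- vector("list", geom$m)
  ci <- vector("list", geom$m)
  vi <- vector("list", geom$m)
  row <- 0L
  for (a in seq_len(geom$n_angles)) {
    theta <- (a - 1) * pi / geom$n_angles
    u <- c(-sin(theta), cos(theta))
    w <- c(cos(theta), sin(theta))
    for (b in seq_len(geom$n_bins)) {
      row <- row + 1L
      offs <- (b - (geom$n_bins + 1) / 2) * geom$bin_width
      o <- offs * w
      ts <- numeric(0)
      ok <- TRUE
      if (abs(u[1]) > 1e-12) {
        ts <- c(ts, (xlines - o[1]) / u[1])
      } else if (o[1] < org[1] || o[1] >= xmax) ok <- FALSE
      if (ok && abs(u[2]) > 1e-12) {
        ts <- c(ts, (ylines - o[2]) / u[2])
      } else if (ok && (o[2] < org[2] || o[2] >= ymax)) ok <- FALSE
      if (!ok || length(ts) < 2L) next
      ts <- sort(ts)
      len <- diff(ts)
      keep <- len > 1e-12
      if (!any(keep)) next
      tm <- (ts[-length(ts)] + ts[-1L]) / 2
      mx <- o[1] + tm * u[1]
      my <- o[2] + tm * u[2]
      ix <- floor((mx - org[1]) / px)
      iy <- floor((my - org[2]) / px)
      keep <- keep & ix >= 0 & ix < nx & iy >= 0 & iy < ny
      if (!any(keep)) next
      ri[[row]] <- rep.int(row, sum(keep))
      ci[[row]] <- as.integer(iy[keep]) * nx + as.integer(ix[keep]) + 1L
      vi[[row]] <- len[keep]
    }
  }
  entries <- Matrix::sparseMatrix(
    i = unlist(ri), j = unlist(ci), x = unlist(vi),
    dims = c(geom$m, geom$n))
  structure(list(entries = entries, geometry = geom, provenance = "exact"),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("System matrix (%s): %d x %d, %d nonzeros\n",
              x$provenance, nrow(x$entries), ncol(x$entries),
              length(x$entries@x)))
  print(x$geometry)
  invisible(x)
}

as_system_matrix <- function(entries, geom, provenance = "exact") {
  structure(list(entries = methods::as(entries, "CsparseMatrix"),
                 geometry = geom, provenance = provenance),
            class = "system_matrix")
}

sysmat_entries <- function(D) {
  if (inherits(D, "system_matrix")) D$entries else D
}

#' Forward projection y = D x
#'
#' @param D A `system_matrix` (or any m x n matrix).
#' @param x Activity vector of length n (or an `activity_image`).
#' @return Numeric length-m sinogram vector (noiseless kind).
#' @export
forward_project <- function(D, x) {
  E <- sysmat_entries(D)
  x <- as_activity_vector(x)
  if (length(x) != ncol(E)) stop("dimension mismatch: length(x) != ncol(D)")
  as.numeric(E %*% x)
}

#' Back projection D' y
#'
#' The adjoint of [forward_project()]; the result lives on the image grid but
#' is not constrained to be a valid (nonnegative) activity image.
#'
#' @param D A `system_matrix` (or any m x n matrix).
#' @param y Sinogram vector of length m.
#' @return Numeric length-n image-shaped vector.
#' @export
back_project <- function(D, y) {
  E <- sysmat_entries(D)
  y <- as_sinogram_vector(y)
  if (length(y) != nrow(E)) stop("dimension mismatch: length(y) != nrow(D)")
  as.numeric(Matrix::crossprod(E, y))
}

#' Filtered back projection (initializer)
#'
#' Ramp-filtered (Hann-windowed) parallel-beam FBP used only to initialize
#' the iterative reconstructors; the accuracy contract is deliberately loose.
#' Projections are filtered per angle in the frequency domain and
#' backprojected with linear interpolation over detector offsets; the result
#' is clipped to be nonnegative and, when the data have positive total
#' counts, rescaled so its forward projection matches the total counts.
#'
#' @param y Sinogram vector (corrected or noiseless), length m.
#' @param geom The [scan_geometry()].
#' @param D Optional `system_matrix` used only for the count rescaling.
#' @return Numeric length-n nonnegative image vector.
#' @export
fbp_reconstruct <- function(y, geom, D = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  y <- as_sinogram_vector(y)
  if (length(y) != geom$m) stop("dimension mismatch")
  if (geom$n_angles < 2L) stop("FBP requires at least 2 angles")
  nb <- geom$n_bins; na <- geom$n_angles; bw <- geom$bin_width
  sino <- matrix(y, nrow = nb, ncol = na)  # bin-fastest layout

  # Hann-windowed ramp filter, zero-padded FFT
  npad <- 2^ceiling(log2(max(64L, 2L * nb)))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * bw)
  ramp <- abs(freq)
  hann <- 0.5 * (1 + cos(pi * freq / max(abs(freq))))
  filt <- ramp * hann
  fsino <- matrix(0, nrow = nb, ncol = na)
  for (a in seq_len(na)) {
    p <- c(sino[, a], rep(0, npad - nb))
    fp <- Re(stats::fft(stats::fft(p) * filt, inverse = TRUE)) / npad
    fsino[, a] <- fp[seq_len(nb)]
  }

  # backproject with linear interpolation in detector offset
  px <- geom$pixel_size
  org <- grid_origin(geom)
  ix <- rep(seq_len(geom$grid_nx) - 0.5, times = geom$grid_ny)
  iy <- rep(seq_len(geom$grid_ny) - 0.5, each = geom$grid_nx)
  xc <- org[1] + ix * px
  yc <- org[2] + iy * px
  img <- numeric(geom$n)
  for (a in seq_len(na)) {
    theta <- (a - 1) * pi / na
    tt <- xc * cos(theta) + yc * sin(theta)
    bpos <- tt / bw + (nb + 1) / 2
    b0 <- floor(bpos)
    wgt <- bpos - b0
    v0 <- ifelse(b0 >= 1 & b0 <= nb, fsino[pmin(pmax(b0, 1L), nb), a], 0)
    v1 <- ifelse(b0 + 1 >= 1 & b0 + 1 <= nb,
                 fsino[pmin(pmax(b0 + 1L, 1L), nb), a], 0)
    img <- img + (1 - wgt) * v0 + wgt * v1
  }
  img <- img * pi / na
  img[img < 0] <- 0
  if (!is.null(D) && sum(img) > 0) {
    proj <- forward_project(D, img)
    tot <- sum(pmax(y, 0))
    if (sum(proj) > 0 && tot > 0) img <- img * tot / sum(proj)
  }
  img
}
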