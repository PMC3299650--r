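#' Parallel-beam scan geometry
#'
#' Defines the image grid and the parallel-beam projection layout that fix the
#' index spaces of the reconstruction problem: the activity image is a length
#' `n = grid_nx * grid_ny` vector (row-major: the x index varies fastest,
#' pixel (0,0) at the min-x/min-y corner) and the sinogram is a length
#' `m = n_angles * n_bins` vector (angle-major: all bins of the first angle,
#' then the second, ...).
#'
#' Coordinates place the image centered on the origin, pixel boundaries at
#' `-grid_nx*pixel_size/2 + i*pixel_size`.  Projection angle 0 sends rays
#' parallel to the y-axis; angles are uniform over `[0, pi)`.  The detector
#' offset of bin `b` (1-based) is `(b - (n_bins+1)/2) * bin_width`, so the
#' bin array is centered on the origin.
#'
#' @param grid_nx,grid_ny Number of image pixels along x and y.
#' @param n_angles Number of projection angles spanning `[0, pi)`.
#' @param n_bins Number of detector bins per angle.
#' @param pixel_size Pixel side length (arbitrary length units).
#' @param bin_width Detector bin width; defaults to `pixel_size`.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(64, 64, n_angles = 60, n_bins = 95)
#' g$n  # 4096 voxels
#' g$m  # 5700 bins
#' @export
scan_geometry <- function(grid_nx, grid_ny, n_angles, n_bins,
                          pixel_size = 1.0, bin_width = pixel_size) {
  grid_nx <- as.integer(grid_nx); grid_ny <- as.integer(grid_ny)
  n_angles <- as.integer(n_angles); n_bins <- as.integer(n_bins)
  if (grid_nx < 1L || grid_ny < 1L)
    stop("grid dimensions must be positive")
  if (n_angles < 1L || n_bins < 1L)
    stop("n_angles and n_bins must be positive")
  if (pixel_size <= 0 || bin_width <= 0)
    stop("pixel_size and bin_width must be positive")
  g <- list(grid_nx = grid_nx, grid_ny = grid_ny,
            pixel_size = pixel_size,
            n_angles = n_angles, n_bins = n_bins,
            bin_width = bin_width,
            n = grid_nx * grid_ny,
            m = n_angles * n_bins)
  class(g) <- "scan_geometry"
  g
}

#' Default desk-scale geometry: 64x64 grid, 60 angles, 95 bins
#' @param ... Overrides passed to [scan_geometry()].
#' @return A `scan_geometry`.
#' @export
default_geometry <- function(...) {
  args <- utils::modifyList(
    list(grid_nx = 64L, grid_ny = 64L, n_angles = 60L, n_bins = 95L),
    list(...))
  do.call(scan_geometry, args)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("Parallel-beam scan geometry: %d x %d grid (pixel %g), %d angles x %d bins (bin %g)\n",
              x$grid_nx, x$grid_ny, x$pixel_size,
              x$n_angles, x$n_bins, x$bin_width))
  cat(sprintf("  n = %d image voxels, m = %d sinogram bins\n", x$n, x$m))
  invisible(x)
}

# physical x-extent origin (min corner) of the grid
grid_origin <- function(geom) {
  c(-geom$grid_nx * geom$pixel_size / 2,
    -geom$grid_ny * geom$pixel_size / 2)
}

# Ray for (angle index a, bin index b), both 1-based.
# Angle theta = (a-1)*pi/n_angles; direction (-sin t, cos t) (parallel to the
# y-axis at angle 0); the ray passes through offset*(cos t, sin t).
ray_for_bin <- function(geom, a, b) {
  theta <- (a - 1) * pi / geom$n_angles
  offs <- (b - (geom$n_bins + 1) / 2) * geom$bin_width
  list(origin = c(offs * cos(theta), offs * sin(theta)),
       direction = c(-sin(theta), cos(theta)),
       theta = theta, offset = offs)
}

#' Length of the intersection of a ray with an axis-aligned rectangle
#'
#' The single-ray projector model: the system-matrix entry for (ray, pixel)
#' is the Euclidean length of the segment of the ray inside the pixel.
#' Pixels are half-open boxes `[x, x+dx) x [y, y+dy)`: a ray running exactly
#' along the low edge of a box belongs to that box, one along the high edge
#' contributes 0, so adjacent pixels never double-count a shared boundary.
#'
#' @param rect Numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @param origin Numeric length-2 point on the ray.
#' @param direction Numeric length-2 unit vector.
#' @return Nonnegative scalar; 0 when the ray misses the rectangle.
#' @examples
#' intersection_length(c(0, 0, 1, 1), c(-1, 0.5), c(1, 0))  # 1
#' intersection_length(c(0, 0, 1, 1), c(0, 0), c(1, 1) / sqrt(2))  # sqrt(2)
#' @export
intersection_length <- function(rect, origin, direction) {
  stopifnot(length(rect) == 4L, length(origin) == 2L, length(direction) == 2L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-8)
    stop("direction must be a unit vector")
  lo <- rect[c(1L, 2L)]; hi <- rect[c(3L, 4L)]
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    u <- direction[k]; o <- origin[k]
    if (abs(u) < 1e-12) {
      # parallel to this axis: inside the half-open slab or miss entirely
      if (o < lo[k] || o >= hi[k]) return(0)
    } else {
      t1 <- (lo[k] - o) / u
      t2 <- (hi[k] - o) / u
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1)
      tmax <- min(tmax, t2)
    }
  }
  max(0, tmax - tmin)
}
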