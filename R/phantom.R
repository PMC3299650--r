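# Classic ten-ellipse Shepp-Logan parameter table:
# columns: additive intensity, semi-axis a, semi-axis b, center x0, y0,
# rotation (degrees, counter-clockwise).  Coordinates live in [-1, 1]^2.
shepp_logan_table <- function() {
  matrix(c(
     2.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))
}

#' Shepp-Logan emission phantom
#'
#' Rasterizes the classic ten-ellipse Shepp-Logan head phantom at pixel
#' centers of the grid, mapped to the unit square `[-1, 1]^2`, and clips any
#' tiny negative sums to zero so the result is a valid activity image.
#' Deterministic.
#'
#' @param geom A [scan_geometry()].
#' @return An [activity_image()].
#' @examples
#' g <- scan_geometry(64, 64, n_angles = 60, n_bins = 95)
#' ph <- shepp_logan_phantom(g)
#' range(ph$values)
#' @export
shepp_logan_phantom <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  nx <- geom$grid_nx; ny <- geom$grid_ny
  # pixel centers in [-1, 1]^2 (independent of pixel_size)
  xs <- (rep(seq_len(nx), times = ny) - 0.5) * 2 / nx - 1
  ys <- (rep(seq_len(ny), each = nx) - 0.5) * 2 / ny - 1
  tab <- shepp_logan_table()
  vals <- numeric(geom$n)
  for (e in seq_len(nrow(tab))) {
    A <- tab[e, "A"]; a <- tab[e, "a"]; b <- tab[e, "b"]
    phi <- tab[e, "phi"] * pi / 180
    dx <- xs - tab[e, "x0"]; dy <- ys - tab[e, "y0"]
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    vals[inside] <- vals[inside] + A
  }
  vals[vals < 0] <- 0
  activity_image(vals, geom)
}
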