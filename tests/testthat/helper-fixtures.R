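# Shared in-code fixtures.  Geometries are deliberately small; everything is
# generated deterministically at test time.

tiny_geom <- function() scan_geometry(8, 8, n_angles = 10, n_bins = 11)
small_geom <- function() scan_geometry(16, 16, n_angles = 12, n_bins = 23)
mid_geom <- function() scan_geometry(32, 32, n_angles = 30, n_bins = 47)
toy_geom <- function() scan_geometry(2, 2, n_angles = 3, n_bins = 3)

# cache system matrices across tests (building is deterministic)
.fixture_env <- new.env(parent = emptyenv())
cached_sysmat <- function(geom) {
  key <- sprintf("D_%d_%d_%d_%d", geom$grid_nx, geom$grid_ny,
                 geom$n_angles, geom$n_bins)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_system_matrix(geom)
  .fixture_env[[key]]
}

# brute-force ray length through one pixel by fine sampling; the independent
# oracle for the analytic intersection machinery
sampled_ray_length <- function(rect, origin, direction, step = 1e-4) {
  span <- 4 * max(rect[3] - rect[1], rect[4] - rect[2], 1)
  ts <- seq(-span, span, by = step)
  px <- origin[1] + ts * direction[1]
  py <- origin[2] + ts * direction[2]
  inside <- px >= rect[1] & px < rect[3] & py >= rect[2] & py < rect[4]
  sum(inside) * step
}

# independent dense penalized-WLS solve used as an oracle for iterative paths
dense_pwls_solution <- function(E, y, w, Q, beta) {
  Ed <- as.matrix(E)
  H <- crossprod(Ed, Ed * w) + beta * as.matrix(Q)
  solve(H, as.numeric(crossprod(Ed, w * y)))
}
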