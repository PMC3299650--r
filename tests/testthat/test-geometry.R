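test_that("scan geometry validates and exposes index spaces", {
  g <- scan_geometry(4, 3, n_angles = 5, n_bins = 7)
  expect_equal(g$n, 12L)
  expect_equal(g$m, 35L)
  expect_error(scan_geometry(0, 4, n_angles = 2, n_bins = 3), "positive")
  expect_error(scan_geometry(4, 4, n_angles = 2, n_bins = 3,
                             pixel_size = -1), "positive")
})

test_that("intersection_length handles crossings, diagonals and misses", {
  sq <- c(0, 0, 1, 1)
  expect_equal(intersection_length(sq, c(-1, 0.5), c(1, 0)), 1.0)
  expect_equal(intersection_length(sq, c(0, 0), c(1, 1) / sqrt(2)), sqrt(2),
               tolerance = 1e-12)
  expect_equal(intersection_length(sq, c(-1, 2), c(1, 0)), 0.0)
  # half-open boundary ownership: low edge belongs to the box, high edge not
  expect_equal(intersection_length(sq, c(-1, 0), c(1, 0)), 1.0)
  expect_equal(intersection_length(sq, c(-1, 1), c(1, 0)), 0.0)
  expect_error(intersection_length(sq, c(0, 0), c(2, 0)), "unit")
})

test_that("intersection_length agrees with a fine-sampling oracle", {
  set.seed(11)
  for (i in 1:25) {
    rect <- c(sort(runif(2, -1, 1)), 0, 0)
    rect <- c(rect[1], rect[2], rect[1] + runif(1, 0.2, 1.5),
              rect[2] + runif(1, 0.2, 1.5))
    th <- runif(1, 0, pi)
    o <- runif(2, -1, 1)
    u <- c(cos(th), sin(th))
    expect_equal(intersection_length(rect, o, u),
                 sampled_ray_length(rect, o, u),
                 tolerance = 5e-4)
  }
})

test_that("2x2 one-angle system matrix has unit column-crossing rows", {
  g <- scan_geometry(2, 2, n_angles = 1, n_bins = 2)
  D <- build_system_matrix(g)
  M <- as.matrix(D$entries)
  # each vertical ray crosses the two pixels of one column, length 1 each
  for (r in 1:2) {
    nz <- M[r, M[r, ] > 0]
    expect_length(nz, 2L)
    expect_equal(unname(nz), c(1, 1))
  }
  expect_equal(unname(forward_project(D, rep(1, 4))), c(2, 2))
})

test_that("1x1 single-ray system matrix equals the pixel side length", {
  g <- scan_geometry(1, 1, n_angles = 1, n_bins = 1, pixel_size = 2.5)
  D <- build_system_matrix(g)
  expect_equal(as.numeric(D$entries[1, 1]), 2.5)
})

test_that("system-matrix entries match the per-entry ray-pixel oracle", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  org <- robustpet:::grid_origin(g)
  px <- g$pixel_size
  set.seed(5)
  rows <- sample(g$m, 12L)
  for (ri in rows) {
    a <- (ri - 1) %/% g$n_bins + 1
    b <- (ri - 1) %% g$n_bins + 1
    ray <- robustpet:::ray_for_bin(g, a, b)
    for (j in sample(g$n, 10L)) {
      ix <- (j - 1) %% g$grid_nx
      iy <- (j - 1) %/% g$grid_nx
      rect <- c(org[1] + ix * px, org[2] + iy * px,
                org[1] + (ix + 1) * px, org[2] + (iy + 1) * px)
      expect_equal(as.numeric(D$entries[ri, j]),
                   intersection_length(rect, ray$origin, ray$direction),
                   tolerance = 1e-9)
    }
  }
})

test_that("row sums equal the ray's chord length through the grid", {
  g <- small_geom()
  D <- cached_sysmat(g)
  org <- robustpet:::grid_origin(g)
  ext <- c(org, org[1] + g$grid_nx * g$pixel_size,
           org[2] + g$grid_ny * g$pixel_size)
  rs <- Matrix::rowSums(D$entries)
  for (ri in seq(1, g$m, by = 17)) {
    a <- (ri - 1) %/% g$n_bins + 1
    b <- (ri - 1) %% g$n_bins + 1
    ray <- robustpet:::ray_for_bin(g, a, b)
    chord <- intersection_length(c(ext[1], ext[2], ext[3], ext[4]),
                                 ray$origin, ray$direction)
    expect_equal(rs[ri], chord, tolerance = 1e-9)
  }
})

test_that("zero-size geometry is rejected by the builder", {
  expect_error(scan_geometry(0, 0, n_angles = 1, n_bins = 1))
})
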