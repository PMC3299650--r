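test_that("scan protocol validates its fractions and counts", {
  expect_error(scan_protocol(total_counts = 0), "positive")
  expect_error(scan_protocol(random_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scan_protocol(scatter_fraction = -0.1), "\\[0, 1\\]")
})

test_that("simulated counts match the protocol budgets in expectation", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  nreal <- 200L
  proto <- scan_protocol(n_realizations = nreal, seed = 0L)
  tot_p <- numeric(nreal); tot_d <- numeric(nreal)
  for (r in seq_len(nreal) - 1L) {
    sc <- simulate_scan(ph, D, proto, r)
    tot_p[r + 1] <- sum(sc$prompt$values)
    tot_d[r + 1] <- sum(sc$delayed$values)
  }
  # E[sum prompt] = 1e5 * (1 + 0.6 + 0.2), E[sum delayed] = 0.6e5
  se_p <- sd(tot_p) / sqrt(nreal)
  se_d <- sd(tot_d) / sqrt(nreal)
  expect_lt(abs(mean(tot_p) - 180000), 3 * se_p)
  expect_lt(abs(mean(tot_d) - 60000), 3 * se_d)
})

test_that("per-bin counts are Poisson-dispersed at both count scales", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  for (counts in c(1e5, 1e6)) {
    proto <- scan_protocol(total_counts = counts, n_realizations = 150L,
                           seed = 2L)
    Y <- sapply(0:149, function(r)
      simulate_scan(ph, D, proto, r)$prompt$values)
    vm <- apply(Y, 1, var) / pmax(rowMeans(Y), 1e-9)
    expect_gt(mean(vm), 0.85)
    expect_lt(mean(vm), 1.15)
  }
})

test_that("corrected sinogram is the exact subtraction on noiseless input", {
  g <- tiny_geom()
  proto <- scan_protocol(seed = 0L)
  m <- g$m
  trues <- seq_len(m) %% 7
  randoms <- rep(proto$random_fraction * proto$total_counts / m, m)
  scatter <- rep(proto$scatter_fraction * proto$total_counts / m, m)
  prompt <- sinogram(round(trues + randoms + scatter), g, "prompt")
  delayed <- sinogram(round(randoms), g, "delayed")
  y <- correct_sinogram(prompt, delayed, proto)
  expect_equal(y$kind, "corrected")
  expect_equal(y$values,
               round(trues + randoms + scatter) - round(randoms) - scatter)
  expect_error(correct_sinogram(delayed, delayed, proto), "kind")
})

test_that("corrected sinogram is unbiased for the scaled true projection", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  nreal <- 200L
  proto <- scan_protocol(n_realizations = nreal, seed = 5L)
  acc <- matrix(0, g$m, nreal)
  s <- NA
  for (r in seq_len(nreal) - 1L) {
    sc <- simulate_scan(ph, D, proto, r)
    acc[, r + 1] <- correct_sinogram(sc$prompt, sc$delayed, proto)$values
    s <- sc$scale
  }
  target <- s * forward_project(D, ph)
  tot_se <- sd(colSums(acc)) / sqrt(nreal)
  expect_lt(abs(mean(colSums(acc)) - sum(target)), 3 * tot_se)
  z <- (rowMeans(acc) - target) / (apply(acc, 1, sd) / sqrt(nreal))
  expect_lt(mean(abs(z)), 2)  # bin-level z-scores behave like noise
})

test_that("scan realizations are bit-reproducible given (seed, realization)", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  proto <- scan_protocol(n_realizations = 3L, seed = 9L)
  a <- simulate_scan(ph, D, proto, 1L)
  b <- simulate_scan(ph, D, proto, 1L)
  expect_identical(a$prompt$values, b$prompt$values)
  expect_identical(a$delayed$values, b$delayed$values)
  c_ <- simulate_scan(ph, D, proto, 2L)
  expect_false(identical(a$prompt$values, c_$prompt$values))
  expect_error(simulate_scan(ph, D, proto, 5L), "out of range")
  expect_error(simulate_scan(rep(0, g$n), D, proto, 0L), "zero")
})
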