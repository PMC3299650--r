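test_that("initialization: zero start and P(0) = inverse penalty", {
  g <- small_geom()
  D <- cached_sysmat(g)
  pen <- smoothness_penalty(g)
  ssm <- state_space_model()
  y0 <- rep(0, g$m)
  st <- upwls_init(y0, D, pen, ssm, x0_mode = "zero", mode = "dense")
  expect_equal(st$x_hat, rep(0, g$n))
  Q0 <- robustpet:::ridge_augment(pen)
  expect_equal(as.matrix(st$P %*% Q0), diag(g$n), tolerance = 1e-8)
})

test_that("FBP initialization reaches a given tolerance in fewer steps", {
  g <- mid_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  y <- forward_project(D, ph)
  run <- function(mode) suppressWarnings(upwls_reconstruct(
    y, D, beta = 1e-4, ssm = state_space_model(qv = 0, R = 1),
    assumed_error = 0, epsilon = 0, max_iter = 12L, x_true = ph,
    x0_mode = mode, mode = "information"))
  ef <- run("fbp")$trace$normalized_error
  ez <- run("zero")$trace$normalized_error
  first_below <- function(e, tol) {
    k <- which(e < tol)
    if (length(k)) k[1] else length(e) + 1L
  }
  expect_lte(first_below(ef, 0.05), first_below(ez, 0.05))
  expect_lt(min(ef), 0.05)
})

test_that("prediction step: classical and robust covariance inflation", {
  g <- toy_geom()
  D <- cached_sysmat(g)
  pen <- smoothness_penalty(g)
  st0 <- upwls_init(rep(1, g$m), D, pen, state_space_model(),
                    x0_mode = "zero", mode = "dense")
  # Mf = 0, qv = 0: state unchanged
  a <- upwls_update(st0, state_space_model(qv = 0), NULL)
  expect_equal(a$P, st0$P)
  expect_equal(a$x_hat, st0$x_hat)
  # qv = q, Mf = 0: exact P + qI
  b <- upwls_update(st0, state_space_model(qv = 0.25), NULL)
  expect_equal(b$P, st0$P + diag(0.25, 4), tolerance = 1e-12)
  # Mf != 0: prediction dominates the accurate-model prediction (Loewner)
  U <- make_norm_bounded_model(D, 0.2)
  c_ <- upwls_update(st0, state_space_model(qv = 0.25), U)
  ev <- eigen(c_$P - b$P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_gt(max(ev), 0)
})

test_that("correction step: classical limit equals the Kalman update", {
  set.seed(52)
  g <- toy_geom()
  D <- cached_sysmat(g)
  pen <- smoothness_penalty(g)
  ssm <- state_space_model(qv = 0.01, R = 2)
  y <- forward_project(D, c(1, 2, 3, 4)) + 0.1
  st <- upwls_init(y, D, pen, ssm, x0_mode = "zero", mode = "dense")
  st <- upwls_update(st, ssm, NULL)
  P_prior <- st$P; x_prior <- st$x_hat
  st <- upwls_correct(st, y, D, NULL, ssm)
  Ed <- as.matrix(D$entries)
  Rinv <- diag(1 / 2, g$m)
  P_ref <- solve(solve(P_prior) + t(Ed) %*% Rinv %*% Ed)
  x_ref <- x_prior + as.numeric(P_ref %*% t(Ed) %*% Rinv %*% (y - Ed %*% x_prior))
  expect_equal(st$x_hat, x_ref, tolerance = 1e-8)
  expect_equal(st$P, P_ref, tolerance = 1e-8)
  # posterior covariance never exceeds the prior (information grows)
  ev <- eigen(P_prior - st$P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("perfect data drive the correction to the truth as R -> 0", {
  set.seed(53)
  A <- diag(4) + 0.3 * matrix(runif(16), 4, 4)
  D <- Matrix::Matrix(A, sparse = TRUE)
  x_true <- c(2, 1, 4, 3)
  y <- as.numeric(A %*% x_true)
  pen <- Matrix::Diagonal(4, 1)
  errs <- sapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    ssm <- state_space_model(qv = 0, R = eps)
    st <- upwls_init(y, D, pen, ssm, x0_mode = "zero", mode = "dense")
    st <- upwls_correct(st, y, D, NULL, ssm)
    sqrt(sum((st$x_hat - x_true)^2))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("full recursion with Mf = 0 matches the penalized Kalman recursion", {
  set.seed(54)
  g <- toy_geom()
  D <- cached_sysmat(g)
  Ed <- as.matrix(D$entries)
  pen <- smoothness_penalty(g)
  ssm <- state_space_model(qv = 5e-3, R = 1.7)
  y <- forward_project(D, c(2, 1, 3, 2)) + rnorm(g$m, sd = 0.1)
  n_steps <- 6L
  # reference: textbook information-form Kalman with the same prior
  Q0 <- as.matrix(robustpet:::ridge_augment(pen))
  P <- solve(Q0); x <- rep(0, 4)
  st <- upwls_init(y, D, pen, ssm, x0_mode = "zero", mode = "dense")
  for (k in seq_len(n_steps)) {
    P <- P + diag(ssm$qv, 4)
    Pk <- solve(solve(P) + t(Ed) %*% (Ed / 1.7))
    x <- x + as.numeric(Pk %*% t(Ed) %*% ((y - Ed %*% x) / 1.7))
    P <- Pk
    st <- upwls_update(st, ssm, NULL)
    st <- upwls_correct(st, y, D, NULL, ssm)
    expect_equal(st$x_hat, x, tolerance = 1e-8)
    expect_equal(st$P, P, tolerance = 1e-8)
  }
})

test_that("information engine reproduces the dense engine when exact", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  y <- forward_project(D, ph)
  pen <- smoothness_penalty(g)
  run <- function(mode) upwls_reconstruct(
    y, D, penalty = pen, beta = 1, ssm = state_space_model(qv = 0, R = 1),
    assumed_error = 0, epsilon = 0, max_iter = 8L, mode = mode)
  suppressWarnings({
    a <- run("dense"); b <- run("information")
  })
  expect_equal(a$x, b$x, tolerance = 1e-7)
})

test_that("noiseless recursion recovers the phantom and stop rules work", {
  g <- mid_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  y <- forward_project(D, ph)
  fit <- suppressWarnings(upwls_reconstruct(
    y, D, beta = 1e-4, ssm = state_space_model(qv = 0, R = 1),
    assumed_error = 0, epsilon = 0, max_iter = 50L, x_true = ph,
    mode = "information"))
  expect_lt(tail(fit$trace$normalized_error, 1), 0.01)
  expect_true(all(fit$x >= 0))
  # degenerate stop: epsilon = Inf returns after one correction
  one <- upwls_reconstruct(y, D, beta = 1e-4,
                           ssm = state_space_model(qv = 0, R = 1),
                           assumed_error = 0, epsilon = Inf, max_iter = 50L,
                           x_true = ph, mode = "information")
  expect_equal(one$iterations, 1L)
  expect_true(one$converged)
})

test_that("reconstruction under matrix error stays near the accurate-model level", {
  g <- default_geometry()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  proto <- scan_protocol(n_realizations = 1L, seed = 0L)
  sc <- simulate_scan(ph, D, proto, 0L)
  y <- correct_sinogram(sc$prompt, sc$delayed, proto)
  truth <- sc$scale * ph$values
  Dh <- apply_perturbation(D, perturb_system_matrix(D, 0.06, seed = 1L))
  U <- make_norm_bounded_model(D, 0.06, structure = "isotropic")
  up <- suppressWarnings(upwls_reconstruct(y, Dh, U = U, epsilon = 1e-3,
                                           max_iter = 25L, x_true = truth,
                                           mode = "information"))
  em <- mlem_reconstruct(y, Dh, n_iter = 60L, x_true = truth, epsilon = 0)
  e_up <- tail(up$trace$normalized_error, 1)
  e_em <- tail(em$trace$normalized_error, 1)
  expect_lt(e_up, e_em)  # robust recursion beats fully iterated EM here
  up0 <- suppressWarnings(upwls_reconstruct(y, D, U = U, epsilon = 1e-3,
                                            max_iter = 25L, x_true = truth,
                                            mode = "information"))
  # a 6% matrix error moves the robust estimate only slightly
  expect_lt(e_up, 1.2 * tail(up0$trace$normalized_error, 1))
})

test_that("reconstructors are deterministic given identical inputs", {
  g <- tiny_geom()
  D <- cached_sysmat(g)
  ph <- shepp_logan_phantom(g)
  proto <- scan_protocol(total_counts = 2e3, n_realizations = 1L, seed = 4L)
  sc <- simulate_scan(ph, D, proto, 0L)
  y <- correct_sinogram(sc$prompt, sc$delayed, proto)
  f <- function() suppressWarnings(upwls_reconstruct(
    y, D, assumed_error = 0.06, epsilon = 0, max_iter = 5L,
    mode = "information"))$x
  expect_identical(f(), f())
  g2 <- function() mlem_reconstruct(y, D, n_iter = 10L)$x
  expect_identical(g2(), g2())
})
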