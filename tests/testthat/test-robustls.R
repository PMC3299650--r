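make_custom_U <- function(Mf, Ef, Eg = NULL, phi = 1, level = 0.5) {
  if (is.null(Eg)) Eg <- rep(0, nrow(as.matrix(Ef)))
  structure(list(Mf = Mf, Ef = Ef, Eg = Eg, phi = phi,
                 error_level = level, structure = "custom",
                 mf_scale = max(abs(Mf))),
            class = "uncertainty_model")
}

test_that("accurate-model case reduces to ordinary regularized WLS", {
  set.seed(31)
  A <- matrix(rnorm(12), 4, 3)
  b <- rnorm(4)
  Wv <- c(1, 2, 0.5, 1)
  Q <- diag(0.3, 3)
  U0 <- make_norm_bounded_model(Matrix::Matrix(A, sparse = TRUE), 0)
  sol <- robust_ls_solve(A, b, Wv, Q, U0)
  ref <- solve(Q + t(A) %*% diag(Wv) %*% A, t(A) %*% diag(Wv) %*% b)
  expect_equal(sol$x, as.numeric(ref), tolerance = 1e-10)
  expect_equal(sol$lambda, 0)
})

test_that("lambda lower bound and selection rules", {
  expect_equal(lambda_lower_bound(diag(3), matrix(c(1, 0, 0), 3, 1)), 1)
  set.seed(32)
  A <- matrix(rnorm(24), 6, 4)
  b <- rnorm(6)
  U <- make_custom_U(diag(6), diag(4) * 0.3, Eg = rep(0, 4))
  llow <- lambda_lower_bound(diag(6), U$Mf, U$phi)
  expect_equal(select_lambda(A, b, diag(6), diag(0.1, 4), U,
                             robust_solve_params(alpha = 0)), llow)
  expect_equal(select_lambda(A, b, diag(6), diag(0.1, 4), U,
                             robust_solve_params(alpha = 0.5)), 1.5 * llow)
  expect_error(robust_ls_solve(A, b, diag(6), diag(0.1, 4), U,
                               robust_solve_params(lambda = 0.5 * llow)),
               "below")
  # line search is at least as good as the alpha shortcut in G
  gof <- function(lam)
    robustpet:::robust_g_cost(A, b, diag(6), diag(0.1, 4),
                              as.matrix(U$Ef), rep(0, 4),
                              U$phi * as.matrix(U$Mf), lam)
  lam_ls <- select_lambda(A, b, diag(6), diag(0.1, 4), U,
                          robust_solve_params(lambda_mode = "line_search"))
  for (a in c(0.1, 0.5, 1.0))
    expect_lte(gof(lam_ls), gof((1 + a) * llow) + 1e-8)
})

test_that("robust solution never loses to the nominal one in the worst case", {
  # 2 unknowns, 3 equations, Mf = I3, Ef = I2, phi = 1
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  b <- c(1, 2, 2.5)
  Q <- diag(0.1, 2)
  U <- make_custom_U(diag(3), diag(2))
  sol <- robust_ls_solve(A, b, diag(3), Q, U,
                         robust_solve_params(lambda_mode = "line_search"))
  x_nom <- as.numeric(solve(Q + crossprod(A), crossprod(A, b)))
  worst <- function(x, n_pts = 12000L) {
    set.seed(77)
    wc <- 0
    for (i in seq_len(n_pts)) {
      Z <- matrix(rnorm(6), 3, 2)
      s <- svd(Z)$d[1]
      if (s > 1) Z <- Z / s
      r <- (A + Z) %*% x - b
      wc <- max(wc, 0.1 * sum(x^2) + sum(r^2))
    }
    wc
  }
  expect_lte(worst(sol$x), worst(x_nom) + 1e-6)
})

test_that("closed form matches direct minimization of the worst-case cost", {
  # with Mf = I, W = I, Eg = 0 the worst case has the exact SOS form
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  b <- c(1, 2, 2.5)
  Q <- diag(0.1, 2)
  U <- make_custom_U(diag(3), diag(2))
  sol <- robust_ls_solve(A, b, diag(3), Q, U,
                         robust_solve_params(lambda_mode = "line_search"))
  f <- function(x) 0.1 * sum(x^2) +
    (sqrt(sum((A %*% x - b)^2)) + sqrt(sum(x^2)))^2
  op <- stats::optim(c(0, 0), f, method = "BFGS")
  expect_equal(sol$x, op$par, tolerance = 1e-3)
  expect_equal(f(sol$x), op$value, tolerance = 1e-6)
})

test_that("boundary lambda uses the pseudo-inverse branch", {
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  b <- c(1, 2, 2.5)
  U <- make_custom_U(diag(3), diag(2))
  llow <- lambda_lower_bound(diag(3), U$Mf, U$phi)
  sol <- robust_ls_solve(A, b, diag(3), diag(0.1, 2), U,
                         robust_solve_params(lambda = llow))
  expect_true(all(is.finite(sol$x)))
  expect_true(all(is.finite(as.matrix(sol$W_hat))))
})
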