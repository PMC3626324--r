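test_that("single Kaczmarz updates match the hand calculation", {
  sys <- list(W = matrix(2, 1, 1), b = 4)
  r <- art_solve(sys, art_config(relaxation = 1, n_iterations = 1,
                                 nonneg = FALSE))
  expect_equal(r$eta_hat, 2)
  # clamped negative projection stays at zero
  r0 <- art_solve(list(W = matrix(1, 1, 1), b = -1),
                  art_config(relaxation = 1, n_iterations = 5, nonneg = TRUE))
  expect_equal(r0$eta_hat, 0)
  expect_length(r0$residual_history, 5)
})

test_that("ART converges to the direct solution on consistent systems", {
  set.seed(21)
  W <- matrix(stats::rnorm(9), 3, 3) + diag(3) * 3
  eta_true <- c(1, 2, 0.5)
  b <- as.numeric(W %*% eta_true)
  r <- art_solve(list(W = W, b = b),
                 art_config(relaxation = 1, n_iterations = 500,
                            nonneg = FALSE))
  expect_equal(r$eta_hat, solve(W, b), tolerance = 1e-8)
})

test_that("residuals are nonincreasing on consistent nonnegative systems", {
  set.seed(22)
  W <- matrix(stats::runif(40), 5, 8)
  b <- as.numeric(W %*% c(1, 0, 2, 0, 0.5, 0, 0, 1))
  r <- art_solve(list(W = W, b = b),
                 art_config(relaxation = 0.1, n_iterations = 50))
  expect_true(all(diff(r$residual_history) <= 1e-12))
})

test_that("unconstrained ART approaches the minimum-norm solution", {
  set.seed(23)
  for (trial in 1:5) {
    W <- matrix(stats::rnorm(40), 5, 8)
    b <- as.numeric(W %*% stats::rnorm(8))
    r <- art_solve(list(W = W, b = b),
                   art_config(relaxation = 1, n_iterations = 1e4,
                              nonneg = FALSE))
    sv <- svd(W)
    mn <- sv$v %*% ((t(sv$u) %*% b) / sv$d)  # pseudoinverse solution
    expect_equal(r$eta_hat, as.numeric(mn), tolerance = 1e-6)
  }
})

test_that("row scaling leaves the iteration invariant; null rows are skipped", {
  set.seed(24)
  W <- matrix(stats::runif(24), 4, 6)
  b <- as.numeric(W %*% stats::runif(6))
  cfg <- art_config(relaxation = 0.3, n_iterations = 20)
  r1 <- art_solve(list(W = W, b = b), cfg)
  s <- c(10, 0.01, 5, 100)
  r2 <- art_solve(list(W = W * s, b = b * s), cfg)
  expect_equal(r1$eta_hat, r2$eta_hat, tolerance = 1e-12)
  # null row is skipped and counted
  W2 <- rbind(W, 0)
  r3 <- art_solve(list(W = W2, b = c(b, 1)), cfg)
  expect_equal(r3$skipped_rows, 1)
  expect_equal(r3$eta_hat, r1$eta_hat, tolerance = 1e-14)
  expect_error(art_solve(list(W = matrix(0, 2, 3), b = c(1, 1)), cfg),
               "degenerate")
})

test_that("column scaling and support restriction recover the same model", {
  set.seed(25)
  W <- matrix(stats::runif(30), 5, 6)
  eta_true <- c(0, 3, 0, 1, 0, 0)
  b <- as.numeric(W %*% eta_true)
  cfg <- art_config(relaxation = 1, n_iterations = 2000, nonneg = FALSE)
  # identity scale reproduces the plain iteration exactly
  r0 <- art_solve(list(W = W, b = b), cfg)
  r1 <- art_solve(list(W = W, b = b), cfg, column_scale = rep(1, 6))
  expect_equal(r0$eta_hat, r1$eta_hat, tolerance = 1e-14)
  # support restricted to the true support solves exactly
  r2 <- art_solve(list(W = W, b = b), cfg, support = c(2L, 4L))
  expect_equal(r2$eta_hat, eta_true, tolerance = 1e-8)
  expect_error(art_solve(list(W = W, b = b), cfg, support = integer(0)),
               "empty support")
  expect_error(art_solve(list(W = W, b = b), cfg,
                         column_scale = rep(-1, 6)), "column_scale")
})

test_that("relative-error metric implements the support-restricted formula", {
  expect_equal(max_relative_error(c(1, 2), c(1, 2)), 0)
  expect_equal(max_relative_error(c(1, 2), c(1.001, 2), support_floor = 0),
               0.1)
  # support floor hides near-zero reference nodes
  expect_equal(max_relative_error(c(1, 1e-6), c(1.01, 5), 0.01), 1)
  expect_error(max_relative_error(c(0, 0), c(1, 1)), "empty")
  expect_error(max_relative_error(1:3, 1:2), "lengths differ")
})

test_that("localization metrics behave geometrically", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  eta <- c(0, 1, 0, 0)
  expect_equal(localization_error(eta, co, c(0, 0, 0)), 1)
  # translation equivariance
  expect_equal(localization_error(eta, sweep(co, 2, c(-1, 2, 5), "+"),
                                  c(0, 0, 0) + c(-1, 2, 5)), 1)
  expect_error(localization_error(c(0, 0, 0, 0), co, c(0, 0, 0)),
               "all-zero")
  # ground-truth map localizes within one edge length on the phantom
  ph <- small_setup()$ph
  expect_lt(localization_error(ph$fluor$eta, ph$mesh, c(-0.31, -0.02, 1.93)),
            0.4)
  expect_equal(recovered_mass_fraction(ph$fluor$eta, ph$mesh,
                                       c(-0.31, -0.02, 1.93), 0.5), 1)
})

test_that("ART configuration validates its ranges", {
  expect_error(art_config(relaxation = 0), "relaxation")
  expect_error(art_config(relaxation = 2.5), "relaxation")
  expect_error(art_config(n_iterations = 0), "n_iterations")
})
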