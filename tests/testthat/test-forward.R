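test_that("temporal convolution equals the direct double-sum oracle", {
  set.seed(3)
  for (T_ in c(1, 7, 30, 64)) {
    a <- stats::rnorm(T_)
    b <- stats::rnorm(T_)
    dt <- stats::runif(1, 0.5, 20)
    expect_identical(temporal_convolve(a, b, dt), oracle_convolve(a, b, dt))
  }
})

test_that("temporal convolution has the discrete identity and commutes", {
  dt <- 10
  a <- stats::rnorm(20)
  delta <- c(1 / dt, rep(0, 19))
  expect_equal(temporal_convolve(a, delta, dt), a, tolerance = 1e-15)
  b <- stats::rnorm(20)
  expect_equal(temporal_convolve(a, b, dt), temporal_convolve(b, a, dt),
               tolerance = 1e-13)
  # two unit rectangles of width 5 dt convolve to a triangle
  r <- c(rep(1, 5), rep(0, 15))
  tri <- temporal_convolve(r, r, dt)
  expect_equal(tri, oracle_convolve(r, r, dt))
  expect_equal(which.max(tri), 5L)
  expect_equal(max(tri), 5 * dt)
  expect_error(temporal_convolve(1:3, 1:4, 1), "lengths differ")
})

test_that("row-wise convolution agrees with the scalar operator", {
  set.seed(4)
  M <- matrix(stats::rnorm(5 * 16), 5, 16)
  kern <- exp(-(0:15) / 7)
  out <- earlyfmt:::convolve_rows(M, kern, 2.5)
  for (i in 1:5) {
    expect_equal(out[i, ], temporal_convolve(M[i, ], kern, 2.5),
                 tolerance = 1e-13)
  }
})

test_that("weight entries are the gated triple convolution with mass coupling", {
  # single-node system: closed-form check against scalar convolutions
  c0 <- 0.4; cc <- 0.02; tau <- 200; dt <- 10
  sys <- scalar_system(0.5, c0, cc)
  tg <- make_time_grid(dt, 200, 200)
  E <- lifetime_kernel(tau, tg)
  gs <- structure(list(values = matrix(stats::rnorm(20)^2, 1), dt = dt),
                  class = "fmt_greens")
  gd <- structure(list(values = matrix(stats::rnorm(20)^2, 1), dt = dt),
                  class = "fmt_greens")
  W <- build_weight_matrix(gs, gd, E, tg, sys, tau)
  H <- cc * c0 * gd$values[1, ]  # c * (C G_d) for the scalar system
  Q <- oracle_convolve(gs$values[1, ], E, dt)
  ref <- oracle_convolve(Q, H, dt)[tg$gate_index] / (tau * dt)
  expect_equal(W[1, 1], ref, tolerance = 1e-12)
  # eta-free symmetry: swapping the excitation and detector series
  Wswap <- build_weight_matrix(gd, gs, E, tg, sys, tau)
  expect_equal(W[1, 1], Wswap[1, 1], tolerance = 1e-12)
  # a dead lifetime kernel kills every entry
  expect_true(all(build_weight_matrix(gs, gd, 0 * E, tg, sys, tau) == 0))
})

test_that("emission source series follows the yield-scaled convolution", {
  mesh <- two_tet_mesh()
  pf <- property_field()
  sys <- assemble_system(mesh, pf)
  dt <- 10
  tg <- make_time_grid(dt, 100, 100)
  E <- lifetime_kernel(300, tg)
  gx <- structure(list(values = matrix(stats::runif(50), 5), dt = dt),
                  class = "fmt_greens")
  eta <- c(0, 1, 0, 0, 0)
  S <- emission_source_series(eta, 300, gx, E, sys, dt)
  # independent evaluation at one time node from the definition
  k <- 2
  q2 <- oracle_convolve(gx$values[2, ], E, dt)[k]
  ref <- as.matrix(sys$C) %*% (pf$c * eta / 300 * c(0, q2, 0, 0, 0))
  expect_equal(S[, k], ref[, 1], tolerance = 1e-12)
  expect_true(all(emission_source_series(rep(0, 5), 300, gx, E, sys, dt) == 0))
  expect_equal(emission_source_series(2 * eta, 300, gx, E, sys, dt), 2 * S)
  expect_error(emission_source_series(eta, -1, gx, E, sys, dt), "tau")
})

test_that("coupled simulation is linear in the yield and zero without it", {
  s <- small_setup()
  geom <- projection_geometry(n_projections = 2, increment_deg = 180,
                              detectors_per_projection = 8)
  layout <- build_acquisition(s$ph$mesh, s$ph$props, geom)
  m0 <- simulate_measurements(s$prop, s$tg, layout, 0 * s$ph$fluor$eta,
                              560, s$sys)
  expect_true(all(vapply(m0$projections, function(p) all(p$phim == 0),
                         logical(1))))
  m1 <- simulate_measurements(s$prop, s$tg, layout, s$ph$fluor$eta, 560, s$sys)
  m2 <- simulate_measurements(s$prop, s$tg, layout, 2 * s$ph$fluor$eta,
                              560, s$sys)
  for (p in 1:2) {
    expect_equal(m2$projections[[p]]$phim, 2 * m1$projections[[p]]$phim,
                 tolerance = 1e-12)
    expect_equal(m2$projections[[p]]$phix, m1$projections[[p]]$phix)
  }
})

test_that("gated Born prediction matches the coupled forward model", {
  s <- small_setup()
  geom <- projection_geometry(n_projections = 2, increment_deg = 180,
                              detectors_per_projection = 10)
  layout <- build_acquisition(s$ph$mesh, s$ph$props, geom)
  eta <- s$ph$fluor$eta
  meas <- simulate_measurements(s$prop, s$tg, layout, eta, 560, s$sys)
  E <- lifetime_kernel(560, s$tg)
  for (p in 1:2) {
    gs <- propagate(s$prop, s$tg, layout[[p]]$source)
    gd <- batched_detector_fields(s$prop, s$tg, layout[[p]]$det_anchors)
    W <- build_weight_matrix(gs, gd, E, s$tg, s$sys, 560)
    pred <- as.numeric(W %*% eta)
    obs <- meas$projections[[p]]$phim[, s$tg$gate_index]
    expect_lt(max(abs(pred - obs) / pmax(abs(obs), 1e-300)), 0.05)
  }
})

test_that("normalized Born cancels source scale and applies the floor", {
  s <- small_setup()
  tg <- s$tg
  nd <- 4
  set.seed(8)
  W1 <- matrix(stats::runif(nd * 10), nd)
  phix <- c(2, 4, 1, 8) * 1e-4
  phim <- c(1, 4, 2, 0.5) * 1e-7
  fake_meas <- function(phix, phim) {
    px <- matrix(0, nd, tg$n_steps); px[, tg$gate_index] <- phix
    pm <- matrix(0, nd, tg$n_steps); pm[, tg$gate_index] <- phim
    structure(list(projections = list(list(anchors = 1:nd, phix = px,
                                           phim = pm)),
                   time_grid = tg),
              class = "fmt_measurements")
  }
  ws <- normalized_born(list(W1), fake_meas(phix, phim), tg)
  expect_equal(ws$b, phim / phix)
  # a pair measuring phim = phix normalizes to exactly 1
  ws1 <- normalized_born(list(W1), fake_meas(phix, phix), tg)
  expect_equal(ws1$b, rep(1, nd))
  # scaling one source's impulse magnitude leaves the system unchanged
  ws10 <- normalized_born(list(10 * W1), fake_meas(10 * phix, 10 * phim), tg)
  expect_equal(ws10$W, ws$W, tolerance = 1e-14)
  expect_equal(ws10$b, ws$b, tolerance = 1e-14)
  # zero excitation at one pair excludes it, others unchanged
  phix0 <- phix; phix0[2] <- 0
  wse <- normalized_born(list(W1), fake_meas(phix0, phim), tg)
  expect_equal(nrow(wse$W), 3)
  expect_equal(wse$n_excluded, 1)
  expect_false(wse$pairs$usable[2])
  expect_equal(wse$b, (phim / phix0)[-2])
  expect_error(normalized_born(list(W1), fake_meas(0 * phix, phim), tg),
               "degenerate")
})

test_that("measurement noise is proportional, seeded and unbiased", {
  expect_identical(add_noise(c(1, 2, 3), 0, 1), c(1, 2, 3))
  x <- rep(1, 1e4)
  y1 <- add_noise(x, 0.1, 99)
  y2 <- add_noise(x, 0.1, 99)
  expect_identical(y1, y2)
  expect_lt(abs(mean(y1) - 1), 0.004)
  expect_lt(abs(stats::sd(y1) - 0.1), 0.005)
  # measurement-set method perturbs only the gate column
  s <- small_setup()
  geom <- projection_geometry(n_projections = 1, increment_deg = 360,
                              detectors_per_projection = 5)
  layout <- build_acquisition(s$ph$mesh, s$ph$props, geom)
  m <- simulate_measurements(s$prop, s$tg, layout, s$ph$fluor$eta, 560, s$sys)
  mn <- add_noise(m, 0.1, 5)
  g <- s$tg$gate_index
  expect_false(all(mn$projections[[1]]$phim[, g] ==
                   m$projections[[1]]$phim[, g]))
  expect_identical(mn$projections[[1]]$phim[, -g],
                   m$projections[[1]]$phim[, -g])
  expect_identical(mn$projections[[1]]$phix, m$projections[[1]]$phix)
})
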