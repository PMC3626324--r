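test_that("time grid indexing and gate snapping follow the convention", {
  tg <- make_time_grid(10, 300, 300)
  expect_equal(tg$n_steps, 30L)
  expect_equal(tg$gate_index, 30L)  # 1-based time node at t = 300 ps
  expect_equal(tg$times[tg$gate_index], 300)
  tg2 <- make_time_grid(10, 600, 300)
  expect_equal(tg2$n_steps, 60L)
  expect_equal(tg2$gate_index, 30L)
  # non-commensurate gate snaps to the nearest node with a warning
  expect_warning(tg3 <- make_time_grid(7, 300, 300), "snapped")
  expect_equal(tg3$gate_index, 43L)
  expect_equal(tg3$gate_time, 301)
  expect_error(make_time_grid(10, 300, 400), "exceeds t_end")
  expect_error(make_time_grid(0, 300, 300), "dt must be > 0")
})

test_that("lifetime kernel is the exponential decay on the lag grid", {
  tg <- make_time_grid(10, 300, 300)
  E <- lifetime_kernel(100, tg)
  expect_equal(E[1], 1)            # zero lag
  expect_equal(E[11], exp(-1))     # lag tau = 100 ps
  expect_true(all(diff(E) < 0))
  expect_error(lifetime_kernel(0, tg), "tau")
})

test_that("point sources are delta loads one mean free path inside", {
  s <- homog_setup()
  src <- point_source_vector(s$ph$mesh, c(1.2, 0, 1.5), s$ph$props)
  expect_equal(src$depth, 0.1)  # 1/mu_s' at background mu_s' = 10
  expect_length(src$node, 1)
  src2 <- point_source_vector(s$ph$mesh, c(-1.2, 0, 1.5), s$ph$props)
  expect_false(src$node == src2$node)
  # the realised load has exactly one nonzero entry
  f <- earlyfmt:::source_slot_fun(src, nrow(s$ph$mesh$node_coords), 30)
  expect_equal(sum(f(1) != 0), 1)
  expect_null(f(2))
})

test_that("propagation reproduces the scalar implicit-Euler recurrence", {
  k0 <- 0.7; c0 <- 2.3; dt <- 5
  sys <- scalar_system(k0, c0)
  tg <- make_time_grid(dt, 50, 50)
  prop <- make_propagator(sys, dt)
  S <- matrix(c(1, 0.3, 0, 0, 0.1, 0, 0, 0, 0, 0), 1, 10)
  g <- propagate(prop, tg, S)
  ref <- numeric(10); prev <- 0
  for (k in 1:10) {
    prev <- (c0 / dt * prev + S[1, k]) / (k0 + c0 / dt)
    ref[k] <- prev
  }
  expect_equal(as.numeric(g$values), ref, tolerance = 1e-14)
  # zero source gives an identically zero field
  g0 <- propagate(prop, tg, matrix(0, 1, 10))
  expect_true(all(g0$values == 0))
})

test_that("diffusionless limit accumulates the source through C", {
  mesh <- two_tet_mesh()
  pf <- property_field()
  sysC <- assemble_system(mesh, pf)
  sys0 <- structure(list(K = sysC$K * 0, C = sysC$C, props = pf),
                    class = "fmt_system")
  dt <- 4
  tg <- make_time_grid(dt, 20, 20)
  prop <- make_propagator(sys0, dt)
  S <- matrix(0, 5, 5); S[2, 1] <- 1; S[4, 3] <- 0.5
  g <- propagate(prop, tg, S)
  Cinv <- solve(as.matrix(sysC$C))
  ref <- matrix(0, 5, 5); acc <- numeric(5)
  for (k in 1:5) {
    acc <- acc + dt * (Cinv %*% S[, k])[, 1]
    ref[, k] <- acc
  }
  expect_equal(g$values, ref, tolerance = 1e-10)
})

test_that("fields are reciprocal between source and probe nodes", {
  s <- homog_setup()
  co <- s$ph$mesh$node_coords
  a <- nearest_node(s$ph$mesh, c(0.5, 0.2, 1.2))
  b <- nearest_node(s$ph$mesh, c(-0.4, -0.3, 1.9))
  ga <- propagate(s$prop, s$tg, a)
  gb <- propagate(s$prop, s$tg, b)
  scale <- max(abs(ga$values[b, ]))
  expect_lt(max(abs(ga$values[b, ] - gb$values[a, ])) / scale, 1e-10)
})

test_that("implicit stepping stays finite from 1 to 100 ps steps", {
  s <- homog_setup()
  src <- point_source_vector(s$ph$mesh, c(1.2, 0, 1.5), s$ph$props)
  for (dt in c(1, 100)) {
    tg <- make_time_grid(dt, 10 * dt, 10 * dt)
    prop <- make_propagator(s$sys, dt)
    g <- propagate(prop, tg, src)
    expect_true(all(is.finite(g$values)))
  }
})

test_that("one factorization serves all sources, detectors and steps", {
  s <- homog_setup()
  prop <- make_propagator(s$sys, 10)
  n0 <- prop$counts$solves
  invisible(propagate(prop, s$tg, 10L))
  invisible(propagate(prop, s$tg, 20L))
  invisible(batched_detector_fields(prop, s$tg, c(30L, 40L, 50L)))
  expect_equal(prop$counts$factorizations, 1L)
  expect_equal(prop$counts$solves - n0, 3L * s$tg$n_steps)
})

test_that("batched detector solves equal sequential per-detector solves", {
  s <- homog_setup()
  anchors <- vapply(list(c(1.2, 0, 1.5), c(0, 1.2, 1.8), c(-1.2, 0, 1.2),
                         c(0, -1.2, 2.1), c(0.85, 0.85, 1.5)),
                    function(p) point_source_vector(s$ph$mesh, p,
                                                    s$ph$props)$node,
                    integer(1))
  st <- batched_detector_fields(s$prop, s$tg, anchors)
  ref <- lapply(anchors, function(a) propagate(s$prop, s$tg, a)$values)
  scale <- max(abs(ref[[1]]))
  for (d in seq_along(anchors)) {
    expect_lt(max(abs(st$values[, , d] - ref[[d]])) / scale, 1e-12)
  }
  # batch of one is exactly a single propagation
  one <- batched_detector_fields(s$prop, s$tg, anchors[2])
  expect_lt(max(abs(one$values[, , 1] - ref[[2]])) / scale, 1e-12)
  # permuting detectors permutes the output, values unchanged
  perm <- c(3L, 1L, 5L, 4L, 2L)
  stp <- batched_detector_fields(s$prop, s$tg, anchors[perm])
  expect_equal(stp$values, st$values[, , perm])
  expect_warning(batched_detector_fields(s$prop, s$tg, c(anchors, anchors[1])),
                 "deduplicated")
})

test_that("single-precision stepping rounds the state to float32", {
  s <- homog_setup()
  gd <- propagate(s$prop, s$tg, 5L, precision = "double")
  gs <- propagate(s$prop, s$tg, 5L, precision = "single")
  expect_identical(gs$values, as_single(gs$values))
  expect_false(identical(gs$values, gd$values))
  expect_lt(max(abs(gs$values - gd$values)) / max(abs(gd$values)), 1e-5)
})
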