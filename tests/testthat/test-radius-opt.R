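test_that("outside-radius distortion matches moments and quadrature", {
  # empty integration range at the boundary
  expect_equal(distortion_outside(1, 64, 1), 0)
  expect_equal(distortion_outside(1, 16, 2), 0)
  # at r = 0 the expression is E[y^2], the Beta(m/2, n/2) mean m/D
  expect_equal(distortion_outside(0, 64, 1), 1 / 64, tolerance = 1e-10)
  expect_equal(distortion_outside(0, 16, 4), 4 / 16, tolerance = 1e-10)
  # closed incomplete-beta form as the independent oracle:
  # integral(r,1) (y-r)^2 p dy expanded in truncated moments of Beta(a, b)
  closed_tail <- function(r, n, m) {
    a <- m / 2
    b <- n / 2
    m2 <- a / (a + b) * stats::pbeta(r^2, a + 1, b, lower.tail = FALSE)
    m1 <- exp(lbeta(a + 0.5, b) - lbeta(a, b)) *
      stats::pbeta(r^2, a + 0.5, b, lower.tail = FALSE)
    m0 <- stats::pbeta(r^2, a, b, lower.tail = FALSE)
    m2 - 2 * r * m1 + r^2 * m0
  }
  for (cfg in list(c(64, 1, 0.2), c(64, 1, 0.5), c(256, 16, 0.3))) {
    D <- cfg[1]
    m <- cfg[2]
    r <- cfg[3]
    n <- D - m
    tail_mass <- 1 - psqrtbeta(r, n, m)
    expect_equal(
      distortion_outside(r, D, m),
      closed_tail(r, n, m) / tail_mass,
      tolerance = 1e-8
    )
  }
})

test_that("complete error function has the right boundaries and shape", {
  mod <- distortion_model(E1 = 2e-4, D = 64, m = 1)
  # at r = 1 the outside term vanishes and F = 1
  expect_equal(total_error(1, mod), 2e-4, tolerance = 1e-12)
  # degenerate inside term: E1 = 0 leaves only the weighted outside error
  mod0 <- distortion_model(0, 64, 1)
  expect_equal(
    total_error(0.3, mod0),
    distortion_outside(0.3, 64, 1) * (1 - psqrtbeta(0.3, 63, 1)),
    tolerance = 1e-10
  )
  expect_error(total_error(0, mod), "r")
  expect_error(total_error(1.2, mod), "r")
})

test_that("sampled error curves are unimodal", {
  for (cfg in list(c(50, 16), c(200, 64), c(500, 256))) {
    ro <- optimize_radius(cfg[1], cfg[2], 1, seed = 17)
    grid <- seq(0.05, 1, by = 0.01)
    E <- total_error(grid, distortion_model(ro$E1, cfg[2], 1))
    expect_true(is_unimodal(E, tol = 1e-6))
  }
})

test_that("bounded minimization agrees with a dense grid search", {
  ro <- optimize_radius(200, 64, 1, gamma = 0.1, seed = 5)
  expect_gt(ro$r_opt, sqrt(1 / 64)) # beyond the typical represented length
  expect_lt(ro$r_opt, 1)
  expect_equal(ro$E_inside, ro$r_opt^2 * ro$E1, tolerance = 1e-12)
  grid <- seq(0.001, 1, by = 0.001)
  Eg <- total_error(grid, distortion_model(ro$E1, 64, 1))
  expect_lte(abs(ro$r_opt - grid[which.min(Eg)]), 0.002)
  # curve in the result brackets the optimum
  expect_true(all(ro$E_total <= ro$curve$E + 1e-15))
})

test_that("whole-vector ensembles optimize to radius one", {
  # D = m: all mass at length exactly 1, so the optimum approaches 1 (the
  # hard-projection model makes the limit approach the boundary from below)
  ro <- optimize_radius(50, 8, 8, seed = 2)
  expect_equal(ro$r_opt, 1, tolerance = 1e-3)
  expect_lte(ro$E_total, ro$E1)
})

test_that("analytic estimate overestimates the error at small radii", {
  # hard-projection assumption vs softer neural saturation: median over seeds
  devs <- vapply(1:5, function(s) {
    ens <- build_ensemble(200, 1, seed = s)
    E1 <- distortion_inside_unit(ens)
    analytic <- total_error(0.05, distortion_model(E1, 64, 1))
    emp <- measure_empirical_distortion(200, 64, 1,
      radius = 0.05,
      trials = 1, seed = s, duration = 2
    )
    analytic - emp
  }, numeric(1))
  expect_gt(median(devs), 0)
})

test_that("heuristic neuron reduction reproduces the printed anchors", {
  expect_identical(reduced_neuron_count(50, 2.89), 6L)
  expect_identical(reduced_neuron_count(50, 1.89), 14L)
  expect_identical(reduced_neuron_count(100, 10, floor_n = 5), 5L)
  expect_identical(reduced_neuron_count(50, 1), 50L)
  expect_error(reduced_neuron_count(50, 0.9), "factor")
})

test_that("channel-radius optimization generalizes the sqrt-beta case", {
  # with no offset, unit scale, and an identity decode, the channel model is
  # the sqrt-beta optimization itself
  ro <- optimize_radius(100, 64, 1, seed = 9)
  rc <- nefradius:::optimize_channel_radius(ro$E1, 1, 0, 64,
    decode = "identity"
  )
  expect_equal(rc, ro$r_opt, tolerance = 5e-3)
  # a constant offset shifts the optimal radius upward
  rc_off <- nefradius:::optimize_channel_radius(ro$E1, 1, 0.3, 64,
    decode = "identity"
  )
  expect_gt(rc_off, rc)
  # square decoding penalizes large radii at least as hard
  rsq <- nefradius:::optimize_channel_radius(ro$E1, 1, 0, 64,
    decode = "square"
  )
  expect_lt(rsq, 1)
})
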