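test_that("LIF rate model matches its closed form", {
  p <- lif_params()
  expect_equal(lif_rate(0.5, p), 0) # below threshold
  expect_equal(lif_rate(1, p), 0) # at threshold
  expect_equal(lif_rate(2, p), 1 / (0.002 + 0.02 * log(2)), tolerance = 1e-12)
  # refractory-limited asymptote, approached from below
  expect_lt(lif_rate(1e9, p), 500)
  expect_gt(lif_rate(1e9, p), 499.9)
  # strictly increasing above threshold
  J <- seq(1.01, 10, by = 0.01)
  expect_true(all(diff(lif_rate(J, p)) > 0))
})

test_that("gain/bias solution pins threshold and maximum rate", {
  p <- lif_params()
  gb <- solve_gain_bias(400, 0, p)
  expect_equal(lif_rate(gb$gain * 0 + gb$bias, p), 0) # at threshold
  expect_equal(lif_rate(gb$gain * 1 + gb$bias, p), 400, tolerance = 1e-9)
  gb <- solve_gain_bias(200, -1, p)
  expect_equal(lif_rate(gb$gain * -1 + gb$bias, p), 0)
  expect_gt(lif_rate(gb$gain * 0 + gb$bias, p), 0) # fires over whole range
  # monotonicity between intercept and max
  gb <- solve_gain_bias(300, 0.5, p)
  mid <- lif_rate(gb$gain * 0.75 + gb$bias, p)
  expect_gt(mid, 0)
  expect_lt(mid, 300)
  expect_error(solve_gain_bias(300, 1, p), "intercept")
})

test_that("ensembles sample encoders, rates, and intercepts as specified", {
  ens <- build_ensemble(200, 1, seed = 0)
  expect_true(all(ens$encoders %in% c(-1, 1)))
  ens2 <- build_ensemble(50, 2, seed = 1)
  expect_equal(sqrt(rowSums(ens2$encoders^2)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(ens2$gains > 0))
  # +1/-1 encoder balance within 3 binomial standard errors
  ens3 <- build_ensemble(1000, 1, seed = 2)
  expect_lt(abs(mean(ens3$encoders == 1) - 0.5), 3 * sqrt(0.25 / 1000))
  # rates within range, and rate at x = r * e_i equals the sampled max rate
  A <- activity_matrix(ens3, matrix(ens3$radius, 1, 1))
  on_dir <- ens3$encoders[, 1] == 1
  expect_equal(A[on_dir, 1], ens3$max_rates[on_dir], tolerance = 0.1)
  # determinism
  expect_identical(
    build_ensemble(20, 3, seed = 5)$encoders,
    build_ensemble(20, 3, seed = 5)$encoders
  )
})

test_that("evaluation-point heuristic and sampler behave as specified", {
  expect_identical(default_eval_count(200, 1), 750L)
  expect_identical(default_eval_count(2000, 1), 4000L)
  expect_identical(default_eval_count(10, 16), 2500L)
  p1 <- sample_eval_points(1000, 1, 1, seed = 0)
  expect_true(all(abs(p1) <= 1))
  expect_lt(abs(mean(p1)), 3 / sqrt(3 * 1000)) # var of U(-1,1) = 1/3
  p2 <- sample_eval_points(10000, 2, 1, seed = 1)
  frac <- mean(rowSums(p2^2) <= 0.25)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  p3 <- sample_eval_points(100, 3, 0.2, seed = 2)
  expect_lte(max(sqrt(rowSums(p3^2))), 0.2)
})

test_that("activity matrix respects thresholds and shape", {
  ens <- build_ensemble(200, 1, seed = 3)
  pts <- sample_eval_points(750, 1, 1, seed = 3)
  A <- activity_matrix(ens, pts)
  expect_identical(dim(A), c(200L, 750L))
  expect_true(all(is.finite(A)) && all(A >= 0))
  expect_error(activity_matrix(ens, matrix(0, 5, 2)), "dimensionality")
})

test_that("decoder solver agrees with an independent ridge oracle", {
  set.seed(11)
  ens <- build_ensemble(20, 1, seed = 11)
  pts <- sample_eval_points(50, 1, 1, seed = 11)
  A <- activity_matrix(ens, pts)
  gamma <- 0.1
  d <- solve_decoders(A, pts, gamma)$decoders
  # oracle: augmented least squares solved by QR, an independent route
  lam <- sqrt(ncol(A) * gamma^2 * max(A)^2)
  aug <- rbind(t(A), lam * diag(nrow(A)))
  rhs <- rbind(pts, matrix(0, nrow(A), 1))
  d_oracle <- qr.solve(aug, rhs)
  expect_equal(d, d_oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("identity and nonlinear decodes reach the expected accuracy", {
  ens <- build_ensemble(200, 1, seed = 4)
  pts <- sample_eval_points(750, 1, 1, seed = 4)
  A <- activity_matrix(ens, pts)
  dec <- solve_decoders(A, pts, 0.1)
  fresh <- sample_eval_points(500, 1, 1, seed = 99)
  est <- t(activity_matrix(ens, fresh)) %*% dec$decoders
  expect_lt(mean(abs(est - fresh)), 0.05)
  # arbitrary function f(x) = x^2 through alternative decoders
  dec2 <- solve_decoders(A, pts^2, 0.1, target_function = "square")
  est2 <- t(activity_matrix(ens, fresh)) %*% dec2$decoders
  expect_lt(sqrt(mean((est2 - fresh^2)^2)), 0.05)
  # overwhelming regularization shrinks decoders to zero
  dhuge <- solve_decoders(A, pts, 1e6)$decoders
  expect_lt(max(abs(dhuge)), 1e-8)
  # unregularized solve on a rank-deficient system reports failure
  A_sing <- matrix(rep(A[1, ], 3), nrow = 3, byrow = TRUE)
  expect_error(solve_decoders(A_sing, pts, 0), "singular")
})

test_that("connection weights factor transforms into the weight matrix", {
  set.seed(8)
  enc <- matrix(sample(c(-1, 1), 10, TRUE), ncol = 1)
  dec <- matrix(rnorm(8), ncol = 1)
  W <- connection_weights(enc, diag(1), dec)
  expect_equal(W, enc %*% t(dec))
  expect_equal(connection_weights(enc, matrix(0, 1, 1), dec), 0 * W)
  expect_equal(connection_weights(enc, 2 * diag(1), dec), 2 * W)
  # a linear transform in the weights equals transforming the decoded value
  P <- matrix(rnorm(9), 3, 3)
  enc3 <- build_ensemble(12, 3, seed = 1)$encoders
  dec3 <- matrix(rnorm(15 * 3), 15, 3)
  a <- rnorm(15)
  expect_equal(
    connection_weights(enc3, P, dec3) %*% a,
    enc3 %*% (P %*% (t(dec3) %*% a)),
    tolerance = 1e-10
  )
  expect_error(connection_weights(enc3, P, dec), "shape")
})

test_that("decoding error with rate noise scales as 1/N", {
  # the noise-inclusive decode error quarters when N quadruples; the pure
  # distortion component alone decays even faster
  ratios <- vapply(1:10, function(s) {
    noisy_decode_mse(100, s) / (4 * noisy_decode_mse(400, s + 100))
  }, numeric(1))
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)
})

test_that("decoding is exactly equivariant in the radius", {
  r <- 0.3
  e1 <- build_ensemble(60, 2, radius = 1, seed = 21)
  er <- build_ensemble(60, 2, radius = r, seed = 21)
  pts1 <- sample_eval_points(200, 2, 1, seed = 21)
  ptsr <- sample_eval_points(200, 2, r, seed = 21)
  expect_equal(ptsr, r * pts1, tolerance = 1e-14)
  d1 <- static_distortion(e1, pts1, 0.1)$decoders
  dr <- static_distortion(er, ptsr, 0.1)$decoders
  x <- matrix(c(0.1, -0.05), 1, 2)
  expect_equal(
    nefradius:::decode_points(er, dr, r * x),
    r * nefradius:::decode_points(e1, d1, x),
    tolerance = 1e-10
  )
})
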