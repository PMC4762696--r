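test_that("representation circuits use the specified radii", {
  net <- build_circuit(circuit_spec("represent",
    D = 64, neurons_per_dim = 20,
    radius_mode = "default", seed = 1
  ))
  expect_identical(net$radii, rep(1, 64))
  expect_identical(net$layers[[1]]$group$n_ens, 64L)
  neto <- build_circuit(circuit_spec("represent",
    D = 64, neurons_per_dim = 20,
    radius_mode = "optimized", seed = 1
  ))
  expect_true(all(neto$radii < 1))
  expect_identical(length(unique(neto$radii)), 1L)
  # degenerate D = 1: the whole (unit) vector in one ensemble
  net1 <- build_circuit(circuit_spec("represent",
    D = 1, neurons_per_dim = 20,
    radius_mode = "optimized", seed = 1
  ))
  expect_equal(net1$radii, 1)
})

test_that("convolution circuits enforce unitarity and the radius modes", {
  spec <- circuit_spec("convolve", D = 16, neurons_per_dim = 30, seed = 2)
  expect_true(is_unitary(spec$fixed_operand))
  bad <- circuit_spec("convolve",
    D = 16, neurons_per_dim = 30,
    fixed_operand = random_pointer(16, seed = 3), seed = 2
  )
  expect_error(build_convolution(bad), "unitary")
  netd <- build_circuit(circuit_spec("convolve",
    D = 16, neurons_per_dim = 30,
    radius_mode = "default", fixed_operand = spec$fixed_operand, seed = 2
  ))
  expect_true(all(netd$radii == 2))
  expect_equal(netd$scale, 1)
  neto <- build_circuit(circuit_spec("convolve",
    D = 16, neurons_per_dim = 30,
    radius_mode = "optimized", fixed_operand = spec$fixed_operand, seed = 2
  ))
  expect_equal(neto$scale, 1 / 4)
  expect_true(all(neto$radii < netd$radii))
})

test_that("convolution network converges to the exact binding", {
  w <- make_unitary(16, seed = 11)
  net <- build_circuit(circuit_spec("convolve",
    D = 16, neurons_per_dim = 200,
    radius_mode = "optimized", fixed_operand = w, seed = 11
  ))
  # with the neural squares replaced by exact squares the wiring computes
  # the circular convolution identically
  X <- t(vapply(1:5, function(s) random_pointer(16, seed = 60 + s),
    numeric(16)
  ))
  U <- sweep(X %*% t(net$layers[[1]]$W_in), 2, net$layers[[1]]$b_in, "+")
  expect_lt(max(abs((U^2) %*% t(net$W_out) - net$ref_fn(X))), 1e-10)
  # idealized (rate-mode, many neurons) decoding approaches the oracle
  sig <- generate_unit_signal(16, 1.5, seed = 12)
  res <- simulate_network(net, sig, mode = "rate", seed = 13)
  expect_lt(sqrt(mean(sim_errors(res, 0.5)^2)), 0.05)
  # the reference is the exact algebra, synapse-filtered: norm preserved
  # under unitary binding before filtering
  ref_raw <- net$ref_fn(sig$samples)
  expect_equal(sqrt(rowSums(ref_raw^2)), rep(1, nrow(ref_raw)),
    tolerance = 1e-9
  )
  expect_equal(
    ref_raw[100, ], circular_convolution(sig$samples[100, ], w),
    tolerance = 1e-10
  )
})

test_that("parabolic multipliers decode products of small inputs", {
  # product of (0.1, 0.1) via the difference of squares of sum/difference
  # channels, each a radius-1 square-decoding ensemble
  group <- nefradius:::make_scalar_layer(2, 100, c(1, 1),
    decode = "square",
    seeds = list(101L, 102L)
  )
  U <- matrix(rep(c(0.2, 0), each = 50), 50, 2) # a+b = 0.2, a-b = 0
  sq <- nefradius:::layer_rates_decode(group, U)
  prod_est <- (sq[50, 1] - sq[50, 2]) / 4
  expect_lt(abs(prod_est - 0.01), 0.005)
})

test_that("dot-product circuits wire the comparison network", {
  spec <- circuit_spec("dot", D = 16, neurons_per_dim = 40, seed = 21)
  netd <- build_circuit(spec)
  expect_identical(netd$radii, rep(1, 32))
  expect_equal(netd$r_out, 1)
  expect_identical(length(netd$layers), 2L)
  neto <- build_circuit(circuit_spec("dot",
    D = 16, neurons_per_dim = 40,
    radius_mode = "optimized", fixed_operand = spec$fixed_operand, seed = 21
  ))
  expect_true(all(neto$radii < 1.35)) # channel values never exceed 1 + |w_i|
  expect_lt(neto$r_out, 1)
  # self-similarity: v . v = 1 for the fixed unit operand fed as input
  v <- spec$fixed_operand
  X <- matrix(v, 400, 16, byrow = TRUE)
  res <- simulate_network(netd, X, mode = "rate", seed = 22)
  expect_equal(res$decoded[400, 1], 1, tolerance = 0.05)
  expect_equal(res$reference[400, 1], 1, tolerance = 1e-6)
})

test_that("optimized radii beat the default for representation", {
  # spiking trials at D = 64, 50 neurons per dimension
  wins <- vapply(1:10, function(s) {
    sig <- generate_unit_signal(64, 1, seed = 100 + s)
    rd <- simulate_network(fixture("rep64_def", {
      build_circuit(circuit_spec("represent",
        D = 64, neurons_per_dim = 50,
        radius_mode = "default", seed = 31
      ))
    }), sig, mode = "spiking", seed = 200 + s)
    ro <- simulate_network(fixture("rep64_opt", {
      build_circuit(circuit_spec("represent",
        D = 64, neurons_per_dim = 50,
        radius_mode = "optimized", seed = 31
      ))
    }), sig, mode = "spiking", seed = 200 + s)
    mean(sim_errors(ro, 0.3)^2) < mean(sim_errors(rd, 0.3)^2)
  }, logical(1))
  expect_gte(sum(wins), 9)
})
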