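# Benchmark circuits: distributed representation, circular-convolution
# binding with a fixed unitary operand, and dot-product comparison.  Each is
# a feedforward net of one-dimensional ensembles; linear transforms (Fourier
# weights, product recombination, summation) live in the connection weights.

#' Circuit specification
#'
#' @param kind `"represent"`, `"convolve"`, or `"dot"`.
#' @param D Vector dimensionality.
#' @param neurons_per_dim Neurons per scalar channel ensemble.
#' @param radius_mode `"default"` (simulator-convention radii) or
#'   `"optimized"` (radii from the distortion-model optimization).
#' @param fixed_operand Second operand for the binding and comparison
#'   circuits; must be unitary for `"convolve"`.  Defaults to a seeded
#'   random unitary (convolve) or random unit (dot) vector.
#' @param gamma Decoder regularization scale.
#' @param params A [lif_params()] object.
#' @param seed Optional integer seed for ensembles and operands.
#' @return Object of class `circuit_spec`.
#' @export
circuit_spec <- function(kind = c("represent", "convolve", "dot"),
                         D, neurons_per_dim = 50,
                         radius_mode = c("default", "optimized"),
                         fixed_operand = NULL, gamma = 0.1,
                         params = lif_params(), seed = NULL) {
  kind <- match.arg(kind)
  radius_mode <- match.arg(radius_mode)
  D <- assert_count(D, "D")
  neurons_per_dim <- assert_count(neurons_per_dim, "neurons_per_dim")
  if (is.null(fixed_operand)) {
    op_seed <- if (is.null(seed)) NULL else seed + 7919L
    fixed_operand <- switch(kind,
      represent = NULL,
      convolve = make_unitary(D, seed = op_seed),
      dot = random_pointer(D, seed = op_seed)
    )
  }
  structure(
    list(
      kind = kind, D = D, neurons_per_dim = neurons_per_dim,
      radius_mode = radius_mode, fixed_operand = fixed_operand,
      gamma = gamma, params = params, seed = seed
    ),
    class = "circuit_spec"
  )
}

new_network <- function(kind, D_in, layers, W_out, ref_fn, n_stages, spec,
                        extra = list()) {
  structure(
    c(
      list(
        kind = kind, D_in = D_in, layers = layers, W_out = W_out,
        ref_fn = ref_fn, n_stages = n_stages, spec = spec
      ),
      extra
    ),
    class = "nef_network"
  )
}

#' @export
print.nef_network <- function(x, ...) {
  nn <- sum(vapply(
    x$layers,
    function(l) l$group$n_ens * l$group$N_per, numeric(1)
  ))
  cat(sprintf(
    "NEF %s circuit: D = %d, %d ensembles in %d layer(s), %d neurons, %s radii\n",
    x$kind, x$spec$D,
    sum(vapply(x$layers, function(l) l$group$n_ens, numeric(1))),
    length(x$layers), nn, x$spec$radius_mode
  ))
  invisible(x)
}

# Shared unit-radius distortion estimates for a given neuron count: E1 for
# identity decodes, E1sq for square decodes.
unit_distortions <- function(N, gamma, params, seed) {
  ens <- build_ensemble(N, 1, 1, params, seed = seed)
  pts <- sample_eval_points(default_eval_count(N, 1), 1, 1, seed = seed)
  list(
    E1 = static_distortion(ens, pts, gamma, identity)$E,
    E1sq = static_distortion(ens, pts, gamma, function(x) x^2)$E
  )
}

#' Build the distributed-representation circuit
#'
#' `D` one-dimensional ensembles, each representing one component of the
#' input vector.  Default mode uses radius 1 for every ensemble (the
#' simulator convention for unit vectors); optimized mode uses the common
#' radius from [optimize_radius()] for `(N, D, m = 1)`, reflecting the
#' square-root-beta distribution of the component magnitudes.
#'
#' @param spec A [circuit_spec()] with `kind = "represent"`.
#' @return An `nef_network`.
#' @export
build_representation <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"), spec$kind == "represent")
  D <- spec$D
  N <- spec$neurons_per_dim
  radius <- if (spec$radius_mode == "optimized" && D > 1) {
    optimize_radius(N, D, 1,
      gamma = spec$gamma, seed = spec$seed,
      params = spec$params
    )$r_opt
  } else {
    1
  }
  seeds <- derive_seeds(spec$seed, D)
  group <- make_scalar_layer(D, N, rep(radius, D),
    decode = "identity",
    params = spec$params, gamma = spec$gamma, seeds = seeds
  )
  new_network(
    kind = "represent", D_in = D,
    layers = list(list(W_in = NULL, b_in = NULL, group = group)),
    W_out = NULL,
    ref_fn = identity,
    n_stages = 1,
    spec = spec,
    extra = list(radii = rep(radius, D))
  )
}

# Real-packed DFT structure: coefficient rows (each row dotted with the
# signal gives one real Fourier coefficient), and the per-product
# recombination/IDFT matrix.
dft_structure <- function(D) {
  j <- 0:(D - 1)
  K <- (D - 1) %/% 2
  even <- D %% 2 == 0
  rows <- list(ones = rep(1, D))
  for (k in seq_len(K)) {
    rows[[paste0("cos", k)]] <- cos(2 * pi * j * k / D)
    rows[[paste0("sin", k)]] <- -sin(2 * pi * j * k / D)
  }
  if (even) rows$nyquist <- (-1)^j
  list(rows = rows, K = K, even = even)
}

#' Build the circular-convolution binding circuit
#'
#' Computes `v` \eqn{\circledast} `w` for a fixed unitary operand `w` as a
#' feedforward network: the discrete Fourier transform of the input enters
#' through the connection weights, each Fourier-coefficient product is
#' computed by a pair of square-decoding scalar ensembles (parabolic
#' multiplier: \eqn{ab = ((a+b)^2 - (a-b)^2)/4}) with the fixed operand's
#' coefficient fed as a constant offset, and the inverse transform returns
#' through the output weights.
#'
#' Default mode follows the simulator convention: forward transform scale 1,
#' inverse scale `1/D`, radius 2 for every multiplication ensemble.
#' Optimized mode scales both transforms by \eqn{1/\sqrt{D}} — which keeps
#' the coefficient vector at unit length so the subvector-length statistics
#' apply — and assigns each multiplication ensemble the radius minimizing
#' its channel's distortion model.
#'
#' @param spec A [circuit_spec()] with `kind = "convolve"`; the fixed
#'   operand must be unitary.
#' @return An `nef_network`.
#' @export
build_convolution <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"), spec$kind == "convolve")
  w <- spec$fixed_operand
  if (is.null(w) || length(w) != spec$D) {
    stop("`fixed_operand` of dimension D is required", call. = FALSE)
  }
  if (!is_unitary(w)) {
    stop("`fixed_operand` must be unitary", call. = FALSE)
  }
  D <- spec$D
  N <- spec$neurons_per_dim
  scl <- if (spec$radius_mode == "optimized") 1 / sqrt(D) else 1
  st <- dft_structure(D)
  wc <- vapply(st$rows, function(r) sum(r * w), numeric(1))

  # products: (row_a, const_c) pairs whose scalar product feeds the output
  prods <- list(list(a = "ones", c = wc[["ones"]], out = "P0"))
  for (k in seq_len(st$K)) {
    ck <- wc[[paste0("cos", k)]]
    dk <- wc[[paste0("sin", k)]]
    prods <- c(prods, list(
      list(a = paste0("cos", k), c = ck, out = paste0("Re", k), sign = +1),
      list(a = paste0("sin", k), c = dk, out = paste0("Re", k), sign = -1),
      list(a = paste0("cos", k), c = dk, out = paste0("Im", k), sign = +1),
      list(a = paste0("sin", k), c = ck, out = paste0("Im", k), sign = +1)
    ))
  }
  if (st$even) {
    prods <- c(prods, list(
      list(a = "nyquist", c = wc[["nyquist"]], out = "Pny")
    ))
  }
  np <- length(prods)

  # channels: two per product, s = scl * (a_row . v) +/- scl * c
  W_in <- matrix(0, 2 * np, D)
  b_in <- numeric(2 * np)
  beta <- numeric(2 * np)
  c0 <- numeric(2 * np)
  for (p in seq_len(np)) {
    row <- st$rows[[prods[[p]]$a]]
    for (s in 1:2) {
      ch <- 2 * (p - 1) + s
      sgn <- if (s == 1) 1 else -1
      W_in[ch, ] <- scl * row
      b_in[ch] <- sgn * scl * prods[[p]]$c
      beta[ch] <- scl * sqrt(sum(row^2))
      c0[ch] <- b_in[ch]
    }
  }

  radii <- if (spec$radius_mode == "default") {
    rep(2, 2 * np)
  } else {
    ud <- unit_distortions(N, spec$gamma, spec$params, spec$seed)
    vapply(seq_len(2 * np), function(ch) {
      optimize_channel_radius(ud$E1sq, beta[ch], c0[ch], D, decode = "square")
    }, numeric(1))
  }

  seeds <- derive_seeds(spec$seed, 2 * np)
  group <- make_scalar_layer(2 * np, N, radii,
    decode = "square",
    params = spec$params, gamma = spec$gamma, seeds = seeds
  )

  # recombination: product p = (sq+ - sq-) / (4 scl^2), then signed sums into
  # real Fourier coefficients of the result and the inverse transform
  M <- matrix(0, np, 2 * np) # products from channel squares
  for (p in seq_len(np)) {
    M[p, 2 * p - 1] <- 1 / (4 * scl^2)
    M[p, 2 * p] <- -1 / (4 * scl^2)
  }
  j <- 0:(D - 1)
  R <- matrix(0, D, np) # output from products (signed IDFT)
  for (p in seq_len(np)) {
    out <- prods[[p]]$out
    sgn <- prods[[p]]$sign %||% 1
    col <- if (out == "P0") {
      rep(1 / D, D)
    } else if (out == "Pny") {
      (-1)^j / D
    } else if (startsWith(out, "Re")) {
      k <- as.integer(sub("Re", "", out))
      2 * cos(2 * pi * j * k / D) / D
    } else {
      k <- as.integer(sub("Im", "", out))
      -2 * sin(2 * pi * j * k / D) / D
    }
    R[, p] <- sgn * col
  }
  W_out <- R %*% M

  circ <- outer(j, j, function(i_, j_) w[(i_ - j_) %% D + 1])
  new_network(
    kind = "convolve", D_in = D,
    layers = list(list(W_in = W_in, b_in = b_in, group = group)),
    W_out = W_out,
    ref_fn = function(X) X %*% t(circ),
    n_stages = 1,
    spec = spec,
    extra = list(radii = radii, scale = scl, channel_beta = beta,
                 channel_offset = c0)
  )
}

#' Build the dot-product comparison circuit
#'
#' Computes the similarity `v . w` with a fixed unit operand `w`:
#' each component product passes through a parabolic multiplier (two
#' square-decoding scalar channels `v_i + w_i` and `v_i - w_i`), and the
#' decoded products project with summing weights onto a single scalar
#' output ensemble.  Default mode uses radius 1 everywhere.  Optimized mode
#' assigns each multiplier channel the radius minimizing its channel
#' distortion model, and optimizes the output radius for the
#' square-root-beta distributed magnitude of the dot product itself.
#'
#' @param spec A [circuit_spec()] with `kind = "dot"`.
#' @return An `nef_network`.
#' @export
build_dot_product <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"), spec$kind == "dot")
  w <- spec$fixed_operand
  if (is.null(w) || length(w) != spec$D) {
    stop("`fixed_operand` of dimension D is required", call. = FALSE)
  }
  D <- spec$D
  N <- spec$neurons_per_dim

  # channels 2i-1, 2i: v_i + w_i and v_i - w_i
  W_in <- matrix(0, 2 * D, D)
  b_in <- numeric(2 * D)
  for (i in seq_len(D)) {
    W_in[2 * i - 1, i] <- 1
    W_in[2 * i, i] <- 1
    b_in[2 * i - 1] <- w[i]
    b_in[2 * i] <- -w[i]
  }

  optimized <- spec$radius_mode == "optimized"
  if (optimized) {
    ud <- unit_distortions(N, spec$gamma, spec$params, spec$seed)
    radii <- vapply(seq_len(2 * D), function(ch) {
      optimize_channel_radius(ud$E1sq, 1, b_in[ch], D, decode = "square")
    }, numeric(1))
    r_out <- optimize_radius(N, D, 1,
      gamma = spec$gamma, seed = spec$seed, params = spec$params
    )$r_opt
  } else {
    radii <- rep(1, 2 * D)
    r_out <- 1
  }

  seeds <- derive_seeds(spec$seed, 2 * D + 1)
  mult_group <- make_scalar_layer(2 * D, N, radii,
    decode = "square",
    params = spec$params, gamma = spec$gamma, seeds = seeds[seq_len(2 * D)]
  )
  # sum of products: dot = sum_i (sq_{2i-1} - sq_{2i}) / 4
  W_sum <- matrix(rep(c(1, -1) / 4, D), nrow = 1)
  out_group <- make_scalar_layer(1, N, r_out,
    decode = "identity",
    params = spec$params, gamma = spec$gamma, seeds = seeds[2 * D + 1]
  )
  new_network(
    kind = "dot", D_in = D,
    layers = list(
      list(W_in = W_in, b_in = b_in, group = mult_group),
      list(W_in = W_sum, b_in = NULL, group = out_group)
    ),
    W_out = NULL,
    ref_fn = function(X) X %*% matrix(w, ncol = 1),
    n_stages = 2,
    spec = spec,
    extra = list(radii = radii, r_out = r_out)
  )
}

#' Build a benchmark circuit from its specification
#'
#' Dispatches to [build_representation()], [build_convolution()], or
#' [build_dot_product()].
#'
#' @param spec A [circuit_spec()].
#' @return An `nef_network`.
#' @export
build_circuit <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  switch(spec$kind,
    represent = build_representation(spec),
    convolve = build_convolution(spec),
    dot = build_dot_product(spec)
  )
}
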