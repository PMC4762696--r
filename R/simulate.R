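#' Exponential synapse model
#'
#' First-order low-pass filter with impulse response \eqn{\exp(-t/\tau)},
#' normalized to unit DC gain in discrete time.  Applied to decoded outputs
#' (and, for spiking neurons, to the spike trains) to model post-synaptic
#' dynamics.
#'
#' @param tau Post-synaptic time constant in seconds.
#' @return Object of class `exp_synapse`.
#' @export
exp_synapse <- function(tau = 0.005) {
  assert_scalar(tau, "tau")
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  structure(list(tau = tau), class = "exp_synapse")
}

#' Filter a signal with an exponential synapse
#'
#' Discrete first-order recursion `y[t] = a y[t-1] + (1 - a) x[t]` with
#' `a = exp(-dt / tau)`; unit DC gain, zero initial state.
#'
#' @param x Numeric vector or `T x k` matrix (filtered per column).
#' @param synapse An [exp_synapse()] object.
#' @param dt Time step in seconds.
#' @return Filtered signal of the same shape.
#' @export
filter_signal <- function(x, synapse, dt) {
  stopifnot(inherits(synapse, "exp_synapse"))
  a <- exp(-dt / synapse$tau)
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) {
      as.numeric(stats::filter((1 - a) * col, a, method = "recursive"))
    })
    matrix(out, nrow = nrow(x))
  } else {
    as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  }
}

# --- stacked scalar-ensemble layers -----------------------------------------
#
# All benchmark circuits are built from layers of one-dimensional ensembles.
# A layer stacks its ensembles into flat per-neuron vectors so the simulator
# works on plain vectorized arithmetic.

make_scalar_layer <- function(n_ens, N_per, radii, decode = "identity",
                              params = lif_params(), gamma = 0.1,
                              seeds = NULL) {
  stopifnot(length(radii) == n_ens, all(radii > 0))
  decode_fn <- switch(decode,
    identity = identity,
    square = function(x) x^2,
    stop("unknown decode: ", decode)
  )
  seeds <- seeds %||% rep(list(NULL), n_ens)
  Q <- default_eval_count(N_per, 1)
  ens_list <- vector("list", n_ens)
  dec_list <- vector("list", n_ens)
  for (e in seq_len(n_ens)) {
    ens <- build_ensemble(N_per, 1, radii[e], params, seed = seeds[[e]])
    pts <- sample_eval_points(Q, 1, radius = radii[e], seed = seeds[[e]])
    sd_ <- static_distortion(ens, pts, gamma, decode_fn)
    ens_list[[e]] <- ens
    dec_list[[e]] <- sd_$decoders$decoders[, 1]
  }
  gains <- unlist(lapply(ens_list, `[[`, "gains"))
  biases <- unlist(lapply(ens_list, `[[`, "biases"))
  encs <- unlist(lapply(ens_list, function(e) e$encoders[, 1]))
  idx <- rep(seq_len(n_ens), each = N_per)
  list(
    n_ens = n_ens, N_per = N_per, radii = radii, decode = decode,
    params = params,
    # scaled encoder: J = esc * u[idx] + bias
    esc = gains * encs / radii[idx],
    bias = biases,
    idx = idx,
    dec = unlist(dec_list),
    ensembles = ens_list
  )
}

# Rate-mode response of a layer to the input time series U (T x n_ens),
# processed in time chunks to bound memory.
layer_rates_decode <- function(layer, U, chunk = 512L) {
  nt <- nrow(U)
  out <- matrix(0, nt, layer$n_ens)
  p <- layer$params
  for (start in seq(1, nt, by = chunk)) {
    idx_t <- start:min(start + chunk - 1, nt)
    # J: neurons x time
    J <- layer$esc * t(U)[layer$idx, idx_t, drop = FALSE] + layer$bias
    A <- matrix(lif_rate(J, p), nrow = length(layer$bias))
    out[idx_t, ] <- t(rowsum(layer$dec * A, layer$idx))
  }
  out
}

# Spiking response: LIF membrane dynamics with sub-step spike-time
# interpolation and exact refractory accounting; spikes are unit-area
# impulses (amplitude 1/dt) decoded like rates.
layer_spikes_decode <- function(layer, U, dt, seed = NULL) {
  p <- layer$params
  if (dt >= p$tau_ref) {
    stop("`dt` must be smaller than the refractory period tau_ref",
      call. = FALSE
    )
  }
  nt <- nrow(U)
  nn <- length(layer$bias)
  v <- with_seed(seed, stats::runif(nn))
  ref <- numeric(nn)
  out <- matrix(0, nt, layer$n_ens)
  Ut <- t(U)[layer$idx, , drop = FALSE]
  inv_dt <- 1 / dt
  for (t in seq_len(nt)) {
    J <- layer$esc * Ut[, t] + layer$bias
    ref <- ref - dt
    delta <- dt - ref
    delta[delta < 0] <- 0
    delta[delta > dt] <- dt
    v <- v + (J - v) * -expm1(-delta / p$tau_rc)
    sp <- v > 1
    if (any(sp)) {
      # time of threshold crossing within the step (backward interpolation)
      t_spike <- dt + p$tau_rc * log1p(-(v[sp] - 1) / (J[sp] - 1))
      ref[sp] <- p$tau_ref + t_spike
      v[sp] <- 0
      a <- numeric(nn)
      a[sp] <- inv_dt
      out[t, ] <- rowsum(layer$dec * a, layer$idx)
    }
  }
  out
}

#' Simulate a benchmark circuit
#'
#' Forward simulation at a fixed time step.  Rate mode evaluates the LIF
#' rate model directly (no spiking noise, so the output error is the pure
#' distortion); spiking mode integrates the LIF membrane dynamics (exact
#' exponential update, sub-step spike timing, reset to zero, refractory
#' clamp) whose time-averaged rates match the rate model under constant
#' input.  Every decoded connection is filtered by the synapse; the exact
#' reference output is passed through the identical filter cascade, which
#' removes the synaptic delay bias from the error.
#'
#' @param network A network from [build_circuit()] (or the individual
#'   builders).
#' @param input A [generate_unit_signal()] object or a `T x D` matrix.
#' @param mode `"rate"` or `"spiking"`.
#' @param synapse An [exp_synapse()] object.
#' @param dt Time step in seconds; must be below the refractory period.
#' @param seed Optional integer seed (spiking initial voltages).
#' @return Object of class `sim_result`: `times`, `decoded` (`T x k`),
#'   `reference` (`T x k`, identically filtered), `mode`, `dt`.
#' @export
simulate_network <- function(network, input, mode = c("spiking", "rate"),
                             synapse = exp_synapse(), dt = 1e-3,
                             seed = NULL) {
  stopifnot(inherits(network, "nef_network"))
  mode <- match.arg(mode)
  X <- if (inherits(input, "unit_signal")) input$samples else as.matrix(input)
  if (ncol(X) != network$D_in) {
    stop("input dimensionality does not match the network", call. = FALSE)
  }
  nt <- nrow(X)
  layer_seeds <- derive_seeds(seed, length(network$layers))
  z <- X
  for (li in seq_along(network$layers)) {
    lay <- network$layers[[li]]
    U <- if (is.null(lay$W_in)) z else z %*% t(lay$W_in)
    if (!is.null(lay$b_in)) {
      U <- sweep(U, 2, lay$b_in, "+")
    }
    raw <- if (mode == "rate") {
      layer_rates_decode(lay$group, U)
    } else {
      layer_spikes_decode(lay$group, U, dt, seed = layer_seeds[[li]])
    }
    z <- filter_signal(raw, synapse, dt)
  }
  decoded <- if (is.null(network$W_out)) z else z %*% t(network$W_out)
  ref <- network$ref_fn(X)
  for (s in seq_len(network$n_stages)) {
    ref <- filter_signal(ref, synapse, dt)
  }
  structure(
    list(
      times = dt * seq_len(nt),
      decoded = decoded,
      reference = ref,
      mode = mode, dt = dt
    ),
    class = "sim_result"
  )
}

#' Per-time-step Euclidean error of a simulation
#'
#' @param result A [simulate_network()] result.
#' @param skip Initial transient to discard, in seconds.
#' @return Numeric vector of Euclidean distances between decoded and
#'   reference output.
#' @export
sim_errors <- function(result, skip = 0) {
  stopifnot(inherits(result, "sim_result"))
  keep <- result$times > skip
  sqrt(rowSums(
    (result$decoded - result$reference)[keep, , drop = FALSE]^2
  ))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "%s-mode simulation: %d steps of %g ms, %d output dimension(s)\n",
    x$mode, length(x$times), 1e3 * x$dt, ncol(x$decoded)
  ))
  invisible(x)
}

#' Export a simulation result as CSV
#'
#' Writes one row per time step: time, decoded components, reference
#' components.
#'
#' @param result A [simulate_network()] result.
#' @param path Output file path.
#' @export
write_sim_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  k <- ncol(result$decoded)
  df <- data.frame(
    time = result$times,
    stats::setNames(
      as.data.frame(result$decoded), paste0("decoded_", seq_len(k))
    ),
    stats::setNames(
      as.data.frame(result$reference), paste0("reference_", seq_len(k))
    )
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
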