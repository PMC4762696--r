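#' Build an NEF ensemble
#'
#' Creates a population of `N` LIF neurons representing an `m`-dimensional
#' value within the given radius.  Encoders are drawn uniformly from the unit
#' sphere (for `m = 1` they are -1 or +1), maximum rates and intercepts
#' uniformly from the ranges in `params`, and gain/bias are solved so that
#' each neuron reaches its maximum rate at normalized input 1.
#'
#' The represented value is divided by `radius` before encoding, so the same
#' neuron parameters describe any radius; decoders are solved against targets
#' in original (unscaled) units.
#'
#' @param N Number of neurons.
#' @param m Represented dimensionality.
#' @param radius Representational radius (positive).
#' @param params A [lif_params()] object.
#' @param seed Optional integer seed; a fixed seed makes the ensemble
#'   deterministic.
#' @return An object of class `nef_ensemble` with fields `N`, `m`, `radius`,
#'   `encoders` (`N x m`, unit rows), `gains`, `biases`, `max_rates`,
#'   `intercepts`, `params`, `seed`.
#' @export
build_ensemble <- function(N, m, radius = 1, params = lif_params(),
                           seed = NULL) {
  N <- assert_count(N, "N")
  m <- assert_count(m, "m")
  assert_scalar(radius, "radius")
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  stopifnot(inherits(params, "lif_params"))
  with_seed(seed, {
    if (m == 1) {
      encoders <- matrix(sample(c(-1, 1), N, replace = TRUE), ncol = 1)
    } else {
      encoders <- matrix(stats::rnorm(N * m), nrow = N, ncol = m)
      encoders <- encoders / sqrt(rowSums(encoders^2))
    }
    max_rates <- stats::runif(N, params$rate_range[1], params$rate_range[2])
    intercepts <- stats::runif(
      N, params$intercept_range[1], params$intercept_range[2]
    )
    gains <- biases <- numeric(N)
    j_max <- lif_current_for_rate(max_rates, params)
    gains <- (j_max - 1) / (1 - intercepts)
    biases <- 1 - gains * intercepts
    structure(
      list(
        N = N, m = m, radius = radius,
        encoders = encoders, gains = gains, biases = biases,
        max_rates = max_rates, intercepts = intercepts,
        params = params, seed = seed
      ),
      class = "nef_ensemble"
    )
  })
}

#' @export
print.nef_ensemble <- function(x, ...) {
  cat(sprintf(
    "NEF ensemble: %d LIF neurons, %d dimension(s), radius %.4g\n",
    x$N, x$m, x$radius
  ))
  invisible(x)
}

#' Default number of decoder evaluation points
#'
#' Heuristic used throughout the benchmarks:
#' `max(2 * N * m, min(max(500 * m, 750), 2500))`.
#'
#' @param N Number of neurons.
#' @param m Represented dimensionality.
#' @return Integer number of evaluation points.
#' @examples
#' default_eval_count(200, 1)  # 750
#' @export
default_eval_count <- function(N, m) {
  N <- assert_count(N, "N")
  m <- assert_count(m, "m")
  as.integer(max(2 * N * m, min(max(500 * m, 750), 2500)))
}

#' Sample decoder evaluation points
#'
#' Draws `Q` points uniformly from the solid `m`-ball of the given radius.
#' For a fixed seed the points at radius `r` are exactly `r` times the points
#' at radius 1, which makes the decoded estimate exactly equivariant in the
#' radius.
#'
#' @param Q Number of points.
#' @param m Dimensionality.
#' @param radius Ball radius.
#' @param seed Optional integer seed.
#' @return `Q x m` matrix of points.
#' @export
sample_eval_points <- function(Q, m, radius = 1, seed = NULL) {
  Q <- assert_count(Q, "Q")
  m <- assert_count(m, "m")
  assert_scalar(radius, "radius")
  with_seed(seed, {
    g <- matrix(stats::rnorm(Q * m), nrow = Q, ncol = m)
    g <- g / sqrt(rowSums(g^2))
    len <- stats::runif(Q)^(1 / m)
    radius * (g * len)
  })
}

#' Activity matrix of an ensemble on evaluation points
#'
#' Evaluates every neuron's LIF rate at every point:
#' `A[i, q] = G[gain_i * (e_i . x_q) / radius + bias_i]`.
#'
#' @param ensemble A [build_ensemble()] object.
#' @param points `Q x m` matrix of evaluation points (original units).
#' @return `N x Q` matrix of firing rates (Hz).
#' @export
activity_matrix <- function(ensemble, points) {
  stopifnot(inherits(ensemble, "nef_ensemble"))
  points <- as.matrix(points)
  if (ncol(points) != ensemble$m) {
    stop("point dimensionality does not match ensemble dimensionality",
      call. = FALSE
    )
  }
  # J: N x Q
  J <- ensemble$gains *
    (ensemble$encoders %*% t(points / ensemble$radius)) + ensemble$biases
  A <- matrix(
    lif_rate(J, ensemble$params),
    nrow = ensemble$N
  )
  A
}

#' Solve regularized least-squares decoders
#'
#' Computes decoding weights by the regularized pseudo-inverse
#' \deqn{D = (A A^\top + Q \gamma^2 \max(A)^2 I)^{-1} A X,}
#' where `max(A)` is the largest element of the activity matrix, `Q` the
#' number of evaluation points, and `X` the `Q x k` matrix of decode targets
#' (the represented points themselves for an identity decode, or `f(x)` for a
#' transformation).
#'
#' @param A `N x Q` activity matrix.
#' @param targets `Q x k` matrix (or length-`Q` vector) of decode targets.
#' @param gamma Regularization scale (nonnegative).
#' @param target_function Optional descriptor stored with the result.
#' @return An object of class `nef_decoders`: list with `decoders`
#'   (`N x k`), `gamma`, `Q`, `target_function`.
#' @export
solve_decoders <- function(A, targets, gamma = 0.1,
                           target_function = "identity") {
  A <- as.matrix(A)
  targets <- as.matrix(targets)
  if (ncol(A) != nrow(targets)) {
    stop("`A` and `targets` must agree on the number of evaluation points",
      call. = FALSE
    )
  }
  assert_scalar(gamma, "gamma")
  if (gamma < 0) stop("`gamma` must be nonnegative", call. = FALSE)
  Q <- ncol(A)
  G <- tcrossprod(A)
  if (gamma > 0) {
    diag(G) <- diag(G) + Q * gamma^2 * max(A)^2
  }
  dec <- tryCatch(
    solve(G, A %*% targets),
    error = function(e) {
      stop(
        "decoder system is singular (gamma = ", gamma, "): ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  structure(
    list(
      decoders = dec, gamma = gamma, Q = Q,
      target_function = target_function
    ),
    class = "nef_decoders"
  )
}

#' Full synaptic connection-weight matrix
#'
#' Folds a linear transform `P` of the represented value into the synaptic
#' weights between two ensembles: `W[i, j] = e_i' P d_j`, the outer product
#' of the postsynaptic encoders with the presynaptic decoders.  With `P` the
#' identity this implements a communication channel.
#'
#' @param post_encoders `N_post x m_post` encoder matrix.
#' @param P `m_post x k_pre` transform matrix.
#' @param pre_decoders `N_pre x k_pre` decoder matrix.
#' @return `N_post x N_pre` weight matrix.
#' @export
connection_weights <- function(post_encoders, P, pre_decoders) {
  post_encoders <- as.matrix(post_encoders)
  P <- as.matrix(P)
  pre_decoders <- as.matrix(pre_decoders)
  if (ncol(post_encoders) != nrow(P) || ncol(P) != ncol(pre_decoders)) {
    stop("incompatible shapes in connection_weights", call. = FALSE)
  }
  post_encoders %*% P %*% t(pre_decoders)
}

# Decoded estimate of an ensemble at given points (original units).
decode_points <- function(ensemble, decoders, points) {
  A <- activity_matrix(ensemble, points)
  t(A) %*% decoders$decoders
}
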