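#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter container for the LIF rate model and the tuning-curve sampler.
#' The threshold current is normalized to 1; per-neuron heterogeneity is
#' carried entirely by the gain and bias (see [solve_gain_bias()]).
#'
#' @param tau_ref Refractory period in seconds.
#' @param tau_rc Membrane time constant in seconds.
#' @param rate_range Interval (Hz) from which each neuron's maximum firing
#'   rate (at normalized input 1) is drawn uniformly.
#' @param intercept_range Interval in normalized represented space from which
#'   each neuron's firing threshold (x-intercept) is drawn uniformly.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_ref = 0.002, tau_rc = 0.02,
                       rate_range = c(200, 400),
                       intercept_range = c(-1, 1)) {
  stopifnot(
    tau_ref > 0, tau_rc > 0,
    length(rate_range) == 2, rate_range[1] > 0,
    rate_range[1] < rate_range[2], rate_range[2] < 1 / tau_ref,
    length(intercept_range) == 2,
    intercept_range[1] < intercept_range[2],
    intercept_range[1] >= -1, intercept_range[2] <= 1
  )
  structure(
    list(
      tau_ref = tau_ref, tau_rc = tau_rc,
      rate_range = as.numeric(rate_range),
      intercept_range = as.numeric(intercept_range)
    ),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters: tau_ref = %g ms, tau_rc = %g ms, max rates %g-%g Hz, intercepts (%g, %g)\n",
    1e3 * x$tau_ref, 1e3 * x$tau_rc, x$rate_range[1], x$rate_range[2],
    x$intercept_range[1], x$intercept_range[2]
  ))
  invisible(x)
}

#' LIF steady-state firing rate
#'
#' Rate approximation of the leaky integrate-and-fire neuron,
#' \deqn{G[J] = 1 / (\tau_{ref} - \tau_{RC} \ln(1 - J_{thr}/J))}
#' for input current `J` above the threshold current \eqn{J_{thr} = 1},
#' and 0 otherwise.
#'
#' @param J Input current (vectorized); unitless, threshold normalized to 1.
#' @param params A [lif_params()] object.
#' @return Firing rates in Hz.
#' @examples
#' lif_rate(2, lif_params())  # 1 / (0.002 + 0.02 * log(2)), about 63 Hz
#' @export
lif_rate <- function(J, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"))
  r <- numeric(length(J))
  fire <- !is.na(J) & J > 1
  r[fire] <- 1 / (params$tau_ref - params$tau_rc * base::log1p(-1 / J[fire]))
  r[is.na(J)] <- NA_real_
  r
}

# Inverse of lif_rate for rate > 0: current producing the given rate.
lif_current_for_rate <- function(rate, params) {
  stopifnot(all(rate > 0), all(rate < 1 / params$tau_ref))
  1 / (-base::expm1((params$tau_ref - 1 / rate) / params$tau_rc))
}

#' Solve for a neuron's gain and bias
#'
#' Finds `(gain, bias)` such that the LIF input current
#' \eqn{J(x) = gain \cdot x + bias} (with `x` the normalized encoded input
#' \eqn{e_i \cdot x / r}) is exactly at the firing threshold at
#' `x = intercept` and produces `max_rate` at `x = 1`.
#'
#' @param max_rate Firing rate at normalized input 1 (Hz).
#' @param intercept Normalized input at which the neuron starts firing; must
#'   be strictly below 1.
#' @param params A [lif_params()] object.
#' @return Named list with elements `gain` and `bias`.
#' @export
solve_gain_bias <- function(max_rate, intercept, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"))
  assert_scalar(max_rate, "max_rate")
  assert_scalar(intercept, "intercept")
  if (intercept >= 1) {
    stop("`intercept` must be < 1 (neuron must fire somewhere in range)",
      call. = FALSE
    )
  }
  if (max_rate <= 0 || max_rate >= 1 / params$tau_ref) {
    stop("`max_rate` must be in (0, 1/tau_ref)", call. = FALSE)
  }
  j_max <- lif_current_for_rate(max_rate, params)
  gain <- (j_max - 1) / (1 - intercept)
  bias <- 1 - gain * intercept
  list(gain = gain, bias = bias)
}
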