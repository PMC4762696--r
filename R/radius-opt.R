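#' Static distortion of an ensemble decode
#'
#' Mean squared residual of the regularized decode over the evaluation
#' points, \eqn{E = \frac{1}{Q}\sum_q \|f(y_q) - \sum_i a_i(y_q) d_i\|^2},
#' with decoders solved on the same points.  This is the noise-free
#' (distortion) component of the representation error.
#'
#' @param ensemble A [build_ensemble()] object.
#' @param points `Q x m` matrix of evaluation points (original units).
#' @param gamma Regularization scale.
#' @param fn Decode target function applied to the points (default identity).
#' @return List with `E` (mean squared error), `decoders`
#'   (the [solve_decoders()] result).
#' @export
static_distortion <- function(ensemble, points, gamma = 0.1, fn = identity) {
  stopifnot(inherits(ensemble, "nef_ensemble"))
  points <- as.matrix(points)
  targets <- as.matrix(fn(points))
  A <- activity_matrix(ensemble, points)
  dec <- solve_decoders(A, targets, gamma,
    target_function = deparse(substitute(fn))
  )
  resid <- targets - t(A) %*% dec$decoders
  list(E = mean(rowSums(resid^2)), decoders = dec)
}

#' Unit-radius inside-radius distortion estimate
#'
#' Estimates the distortion of an identity decode for a unit-radius ensemble.
#' By the radius convention (inputs are normalized by the radius before
#' encoding, decoders solved in original units), the inside-radius distortion
#' at radius `r` is then exactly \eqn{E_{x \le r}(r) = r^2 E_1}.
#'
#' @param ensemble A unit-radius [build_ensemble()] object.
#' @param points Evaluation points in the unit `m`-ball; defaults to
#'   [sample_eval_points()] with [default_eval_count()] points.
#' @param gamma Regularization scale.
#' @return The scalar estimate `E1` (nonnegative).
#' @export
distortion_inside_unit <- function(ensemble, points = NULL, gamma = 0.1) {
  stopifnot(inherits(ensemble, "nef_ensemble"))
  if (abs(ensemble$radius - 1) > 1e-12) {
    stop("`ensemble` must have radius 1", call. = FALSE)
  }
  if (is.null(points)) {
    points <- sample_eval_points(
      default_eval_count(ensemble$N, ensemble$m), ensemble$m,
      radius = 1, seed = ensemble$seed
    )
  }
  static_distortion(ensemble, points, gamma)$E
}

# --- square-root-beta error terms ------------------------------------------

# P(subvector length <= r); n = 0 (whole vector in one ensemble) degenerates
# to a point mass at length 1.
sb_cdf_safe <- function(r, n, m) {
  if (n == 0) as.numeric(r >= 1) else psqrtbeta(r, n, m)
}

# Unnormalized tail error integral(r, 1) (y - r)^2 p_SB(y; n, m) dy by
# adaptive quadrature (the normalized form is in distortion_outside).
sb_tail_integral <- function(r, n, m) {
  if (r >= 1) {
    return(0)
  }
  if (n == 0) {
    return((1 - r)^2)
  }
  stats::integrate(
    function(y) (y - r)^2 * dsqrtbeta(y, n, m),
    lower = r, upper = 1,
    rel.tol = 1e-10, abs.tol = 1e-13, subdivisions = 400L
  )$value
}

#' Distortion from values outside the radius
#'
#' Expected squared error of projecting a subvector of length beyond `r`
#' onto the radius-`r` sphere, conditional on lying outside:
#' \deqn{E_{x>r}(r) = \frac{\int_r^1 (y - r)^2 p_{SB}(y; D-m, m)\,dy}
#'                        {1 - F_{SB}(r; D-m, m)}.}
#' At the upper boundary (radius 1) the integration range is empty and the
#' value is 0 by the limit convention.
#'
#' @param r Radius in `[0, 1]`.
#' @param D Full vector dimensionality.
#' @param m Subvector dimensionality represented by the ensemble.
#' @return Nonnegative conditional squared error.
#' @examples
#' distortion_outside(0, D = 64, m = 1)  # E[y^2] = m/D = 1/64
#' @export
distortion_outside <- function(r, D, m) {
  D <- assert_count(D, "D")
  m <- assert_count(m, "m")
  if (m > D) stop("`m` must not exceed `D`", call. = FALSE)
  assert_scalar(r, "r")
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  n <- D - m
  if (r >= 1) {
    return(0)
  }
  tail_mass <- 1 - sb_cdf_safe(r, n, m)
  if (tail_mass <= 0) {
    return(0)
  }
  sb_tail_integral(r, n, m) / tail_mass
}

#' Radius-dependent distortion model
#'
#' Bundles the empirical unit-radius inside distortion `E1` with the
#' dimensional context `(D, m)` so that [total_error()] can evaluate the
#' complete error function.
#'
#' @param E1 Unit-radius inside-distortion estimate
#'   (from [distortion_inside_unit()]).
#' @param D Full vector dimensionality.
#' @param m Subvector dimensionality.
#' @return An object of class `distortion_model`.
#' @export
distortion_model <- function(E1, D, m) {
  assert_scalar(E1, "E1")
  if (E1 < 0) stop("`E1` must be nonnegative", call. = FALSE)
  D <- assert_count(D, "D")
  m <- assert_count(m, "m")
  if (m > D) stop("`m` must not exceed `D`", call. = FALSE)
  structure(
    list(E1 = E1, D = D, m = m, n = D - m, s = D / m),
    class = "distortion_model"
  )
}

#' Complete radius-dependent error function
#'
#' Weights the inside and outside distortion terms by the probability of a
#' subvector length falling in the respective domain:
#' \deqn{E(r) = r^2 E_1 F_{SB}(r; D-m, m)
#'   + E_{x>r}(r) (1 - F_{SB}(r; D-m, m)).}
#'
#' @param r Radius (vectorized) in `(0, 1]`.
#' @param model A [distortion_model()] object.
#' @return Estimated squared representation error at each `r`.
#' @export
total_error <- function(r, model) {
  stopifnot(inherits(model, "distortion_model"))
  vapply(r, function(ri) {
    assert_scalar(ri, "r")
    if (ri <= 0 || ri > 1) stop("`r` must lie in (0, 1]", call. = FALSE)
    Fin <- sb_cdf_safe(ri, model$n, model$m)
    # the outside term enters as E_out * (1 - F): use the unnormalized tail
    # integral directly so r -> 1 is exact
    ri^2 * model$E1 * Fin + sb_tail_integral(ri, model$n, model$m)
  }, numeric(1))
}

#' Optimize the representational radius of a subvector ensemble
#'
#' Builds a unit-radius ensemble, estimates the inside distortion `E1` once,
#' and minimizes the complete error function [total_error()] over `(0, 1]`
#' by bounded scalar minimization.  Only the activity matrix is empirically
#' estimated; candidate radii reuse the same `E1` through the `r^2` scaling.
#'
#' @param N Neurons in the ensemble.
#' @param D Full vector dimensionality.
#' @param m Subvector dimensionality represented by the ensemble.
#' @param gamma Regularization scale.
#' @param seed Optional integer seed for the ensemble and evaluation points.
#' @param params A [lif_params()] object.
#' @param curve_points Number of radii at which to tabulate the error curve.
#' @param tol Convergence tolerance on the radius.
#' @return Object of class `radius_opt`: list with `r_opt`, `E_total`,
#'   `E_inside` (\eqn{r^2 E_1}), `E_outside` (conditional outside error at
#'   `r_opt`), `E1`, `D`, `m`, `N`, and `curve` (data frame of sampled
#'   `(r, E)` pairs).
#' @export
optimize_radius <- function(N, D, m = 1, gamma = 0.1, seed = NULL,
                            params = lif_params(), curve_points = 101,
                            tol = 1e-4) {
  ens <- build_ensemble(N, m, radius = 1, params = params, seed = seed)
  E1 <- distortion_inside_unit(ens, gamma = gamma)
  model <- distortion_model(E1, D, m)
  opt <- stats::optimize(function(r) total_error(r, model),
    interval = c(1e-3, 1), tol = tol
  )
  if (!is.finite(opt$objective)) {
    stop(
      "radius optimization did not converge: E(", opt$minimum, ") = ",
      opt$objective,
      call. = FALSE
    )
  }
  r_opt <- opt$minimum
  # the curve and boundary: keep r = 1 if it is as good (degenerate D = m)
  if (total_error(1, model) <= opt$objective) {
    r_opt <- 1
  }
  rs <- seq(1 / curve_points, 1, length.out = curve_points)
  structure(
    list(
      r_opt = r_opt,
      E_total = total_error(r_opt, model),
      E_inside = r_opt^2 * E1,
      E_outside = distortion_outside(r_opt, D, m),
      E1 = E1, D = D, m = m, N = N, gamma = gamma, seed = seed,
      curve = data.frame(r = rs, E = total_error(rs, model))
    ),
    class = "radius_opt"
  )
}

#' @export
print.radius_opt <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Optimized radius for %d neurons representing %d of %d dimensions\n",
      "  r_opt = %.4f\n  E(r_opt) = %.3e (inside %.3e, outside %.3e, E1 = %.3e)\n"
    ),
    x$N, x$m, x$D, x$r_opt, x$E_total, x$E_inside, x$E_outside, x$E1
  ))
  invisible(x)
}

#' Heuristically reduced neuron count
#'
#' Because the mean squared representation error is proportional to `1/N`, a
#' measured RMSE reduction by a factor `f` permits reducing the neuron count
#' by `f^2` while retaining the baseline error level:
#' `max(floor, round(N / f^2))` (round-half-to-even).
#'
#' @param N Baseline neuron count.
#' @param factor Measured RMSE reduction factor (at least 1).
#' @param floor_n Minimum neurons to keep (e.g. 5 per dimension for the
#'   dot-product circuit).
#' @return Integer reduced neuron count.
#' @examples
#' reduced_neuron_count(50, 2.89)  # 6
#' reduced_neuron_count(50, 1.89)  # 14
#' @export
reduced_neuron_count <- function(N, factor, floor_n = 1) {
  N <- assert_count(N, "N")
  floor_n <- assert_count(floor_n, "floor_n")
  assert_scalar(factor, "factor")
  if (factor < 1) {
    stop("`factor` must be at least 1 (no reduction justified)", call. = FALSE)
  }
  as.integer(max(floor_n, round(N / factor^2)))
}

# --- generalized channel-radius optimization --------------------------------
#
# The multiplication ensembles of the binding and comparison circuits
# represent scalar channels of the form s = c0 + beta * t, where t is one
# component of a random unit D-vector (symmetric square-root-beta magnitude)
# and c0 is a constant contributed by the fixed operand.  The same
# inside/outside trade-off applies, with the saturation law depending on the
# decoded function: (|s| - r)^2 for an identity decode, (s^2 - r^2)^2 for a
# square decode (decoders for f(s) = s^2 scale with r^2, so the interior
# distortion scales with r^4).

channel_density <- function(s, beta, c0, D) {
  t <- (s - c0) / beta
  out <- numeric(length(s))
  inside <- abs(t) <= 1
  out[inside] <- 0.5 * dsqrtbeta(abs(t[inside]), D - 1, 1) / beta
  out
}

channel_cdf <- function(s, beta, c0, D) {
  t <- pmin(pmax((s - c0) / beta, -1), 1)
  0.5 * (1 + sign(t) * psqrtbeta(abs(t), D - 1, 1))
}

# E(r) for one channel; dens/cdf close over the channel distribution.
channel_total_error <- function(r, E1f, beta, c0, D,
                                decode = c("identity", "square")) {
  decode <- match.arg(decode)
  smax <- abs(c0) + beta
  sat <- if (decode == "identity") {
    function(s) (abs(s) - r)^2
  } else {
    function(s) (s^2 - r^2)^2
  }
  inside_scale <- if (decode == "identity") r^2 else r^4
  p_in <- channel_cdf(r, beta, c0, D) - channel_cdf(-r, beta, c0, D)
  tail <- 0
  if (smax > r) {
    tail <- tail + stats::integrate(
      function(s) sat(s) * channel_density(s, beta, c0, D),
      lower = r, upper = smax,
      rel.tol = 1e-8, abs.tol = 1e-13, subdivisions = 400L,
      stop.on.error = FALSE
    )$value
  }
  if (-smax < -r || c0 - beta < -r) {
    lo <- c0 - beta
    if (lo < -r) {
      tail <- tail + stats::integrate(
        function(s) sat(s) * channel_density(s, beta, c0, D),
        lower = lo, upper = -r,
        rel.tol = 1e-8, abs.tol = 1e-13, subdivisions = 400L,
        stop.on.error = FALSE
      )$value
    }
  }
  inside_scale * E1f * p_in + tail
}

# Optimal radius for a scalar channel s = c0 + beta * t.
optimize_channel_radius <- function(E1f, beta, c0, D,
                                    decode = c("identity", "square"),
                                    tol = 1e-4) {
  decode <- match.arg(decode)
  smax <- abs(c0) + beta
  opt <- stats::optimize(
    function(r) channel_total_error(r, E1f, beta, c0, D, decode),
    interval = c(1e-3 * smax, smax), tol = tol * smax
  )
  if (channel_total_error(smax, E1f, beta, c0, D, decode) <= opt$objective) {
    return(smax)
  }
  opt$minimum
}
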