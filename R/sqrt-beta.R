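#' Length distribution of a random Gaussian vector
#'
#' Density of the Euclidean length of a `D`-dimensional vector whose
#' components are independent \eqn{N(0, \sigma^2)} draws,
#' \deqn{p(x) = k_D \, x^{D-1} \exp(-x^2 / 2\sigma^2),}
#' with normalizing constant
#' \eqn{k_D = 1 / (2^{D/2 - 1} \sigma^D \Gamma(D/2))}.
#' For `D = 1` this is the half-normal distribution and for `D = 2` the
#' Rayleigh distribution.
#'
#' @param x Vector of nonnegative lengths at which to evaluate the density.
#' @param sigma Per-component standard deviation (positive).
#' @param D Dimensionality (positive integer).
#' @param log Return the log-density?
#' @return Density values (0 for negative `x`).
#' @examples
#' dveclength(0, sigma = 1, D = 1)      # sqrt(2/pi), half-normal at 0
#' dveclength(1, sigma = 1, D = 2)      # Rayleigh(1) density at 1
#' @export
dveclength <- function(x, sigma, D, log = FALSE) {
  assert_scalar(sigma, "sigma")
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  D <- assert_count(D, "D")
  logk <- -((D / 2 - 1) * base::log(2) + D * base::log(sigma) + lgamma(D / 2))
  logd <- ifelse(
    x < 0,
    -Inf,
    logk + (D - 1) * base::log(x) - x^2 / (2 * sigma^2)
  )
  # x = 0, D = 1: x^(D-1) = 1, but log(0) * 0 is NaN
  logd[x == 0 & D == 1] <- logk
  if (log) logd else exp(logd)
}

#' The square-root-beta distribution
#'
#' Distribution of the length of an `m`-component subvector of a uniformly
#' random unit vector with `n + m` components.  If \eqn{x} follows this
#' distribution then \eqn{x^2 \sim \mathrm{Beta}(m/2, n/2)}.  The density is
#' \deqn{p(x; n, m) = \frac{2}{B(n/2, m/2)} (x^2)^{(m-1)/2} (1-x^2)^{n/2-1}}
#' on \eqn{[0, 1]} (0 outside), and the distribution function is the
#' regularized incomplete beta function evaluated at \eqn{x^2}.
#'
#' @param x,q Quantiles.
#' @param n Remaining-dimension parameter (positive integer, `D - m`).
#' @param m Subvector-dimension parameter (positive integer).
#' @param log,log.p Work on the log scale?
#' @param lower.tail If `FALSE`, return the upper tail probability.
#' @return `dsqrtbeta` the density, `psqrtbeta` the distribution function
#'   (clamped: 0 below 0, 1 above 1).
#' @seealso [sample_subvector_lengths()] for the generative sampler.
#' @examples
#' dsqrtbeta(0, n = 1, m = 1)     # 2/pi
#' psqrtbeta(0.5, n = 1, m = 1)   # 1/3 (arcsine law)
#' @export
dsqrtbeta <- function(x, n, m, log = FALSE) {
  n <- assert_count(n, "n")
  m <- assert_count(m, "m")
  logd <- rep(-Inf, length(x))
  inside <- x >= 0 & x <= 1
  xi <- x[inside]
  logd[inside] <- base::log(2) - lbeta(n / 2, m / 2) +
    (m - 1) * base::log(xi) + (n / 2 - 1) * base::log1p(-xi^2)
  # 0^0 at the support edges
  if (m == 1) logd[x == 0] <- base::log(2) - lbeta(n / 2, 1 / 2)
  if (n == 2) logd[x == 1] <- base::log(2) - lbeta(1, m / 2)
  if (log) logd else exp(logd)
}

#' @rdname dsqrtbeta
#' @export
psqrtbeta <- function(q, n, m, lower.tail = TRUE, log.p = FALSE) {
  n <- assert_count(n, "n")
  m <- assert_count(m, "m")
  qc <- pmin(pmax(q, 0), 1)
  stats::pbeta(qc^2, m / 2, n / 2, lower.tail = lower.tail, log.p = log.p)
}

#' Sample subvector lengths of random unit vectors
#'
#' Generative sampler for the square-root-beta distribution: draw `D`
#' independent standard-normal components, normalize the vector to unit
#' length, and take the Euclidean norm of its first `m` components.  The
#' samples follow `psqrtbeta(, n = D - m, m = m)`.
#'
#' @param D Total dimensionality.
#' @param m Subvector dimensionality, `1 <= m <= D`.
#' @param count Number of samples.
#' @param seed Optional integer seed (the caller's RNG stream is preserved).
#' @return Numeric vector of `count` lengths in `[0, 1]`.
#' @export
sample_subvector_lengths <- function(D, m, count, seed = NULL) {
  D <- assert_count(D, "D")
  m <- assert_count(m, "m")
  count <- assert_count(count, "count")
  if (m > D) stop("`m` must not exceed `D`", call. = FALSE)
  with_seed(seed, {
    g <- matrix(stats::rnorm(count * D), nrow = count, ncol = D)
    full <- sqrt(rowSums(g^2))
    sub <- sqrt(rowSums(g[, seq_len(m), drop = FALSE]^2))
    sub / full
  })
}
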