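#' Slowly varying random unit-vector trajectory
#'
#' Generates the benchmark input signal: independent Gaussian white noise for
#' each vector component, low-pass filtered with a windowed-sinc FIR filter
#' at the cutoff frequency, then normalized to unit Euclidean length at every
#' time step.  The filter lead-in is generated and discarded so the returned
#' samples are free of the startup transient.
#'
#' @param D Vector dimensionality.
#' @param duration Signal duration in seconds.
#' @param dt Time step in seconds (default 1 ms).
#' @param cutoff Low-pass cutoff frequency in Hz (default 5); must be below
#'   the Nyquist frequency `1 / (2 dt)`.
#' @param seed Optional integer seed; a fixed seed reproduces the signal
#'   bit-exactly.
#' @param filter_order FIR filter order (number of taps minus 1).  The
#'   default gives a transition band of roughly half the cutoff at the
#'   default sampling rate.
#' @return Object of class `unit_signal`: list with `samples`
#'   (`T x D` matrix of unit rows), `times`, `D`, `dt`, `duration`, `cutoff`,
#'   `seed`.
#' @export
generate_unit_signal <- function(D, duration, dt = 1e-3, cutoff = 5,
                                 seed = NULL, filter_order = 800) {
  D <- assert_count(D, "D")
  assert_scalar(duration, "duration")
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (cutoff >= 1 / (2 * dt)) {
    stop("`cutoff` must be below the Nyquist frequency 1/(2*dt)",
      call. = FALSE
    )
  }
  nt <- as.integer(round(duration / dt))
  ntaps <- filter_order + 1
  b <- signal::fir1(filter_order, 2 * cutoff * dt, type = "low")
  raw <- with_seed(seed, {
    matrix(stats::rnorm((nt + ntaps) * D), nrow = nt + ntaps, ncol = D)
  })
  filtered <- apply(raw, 2, function(x) signal::fftfilt(b, x))
  filtered <- filtered[(ntaps + 1):(ntaps + nt), , drop = FALSE]
  norms <- sqrt(rowSums(filtered^2))
  structure(
    list(
      samples = filtered / norms,
      prenorm = filtered,
      times = dt * seq_len(nt),
      D = D, dt = dt, duration = duration, cutoff = cutoff, seed = seed
    ),
    class = "unit_signal"
  )
}

#' @export
print.unit_signal <- function(x, ...) {
  cat(sprintf(
    "Unit-norm signal: %d dimensions, %.3g s at dt = %g ms, %g Hz cutoff\n",
    x$D, x$duration, 1e3 * x$dt, x$cutoff
  ))
  invisible(x)
}
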