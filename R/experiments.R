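# Empirical distortion measurement and the RMSE-distribution experiments
# comparing default against optimized radii (and the heuristically reduced
# neuron count) for the three benchmark circuits.

#' Summarize per-time-step errors
#'
#' Pools per-time-step Euclidean errors across trials and summarizes them by
#' quartiles and the root mean square error.
#'
#' @param samples Numeric vector of per-step errors (pooled over trials).
#' @param trials Number of trials pooled.
#' @param duration_per_trial Trial duration in seconds.
#' @param skip Initial transient that was discarded, in seconds.
#' @return Object of class `error_distribution` with fields `samples`,
#'   `trials`, `duration_per_trial`, `skip`, `quartiles`, `rmse`.
#' @export
error_distribution <- function(samples, trials = 1,
                               duration_per_trial = NA_real_, skip = 0.5) {
  stopifnot(length(samples) > 0, all(samples >= 0))
  structure(
    list(
      samples = samples, trials = trials,
      duration_per_trial = duration_per_trial, skip = skip,
      quartiles = stats::quantile(samples, c(0.25, 0.5, 0.75), names = FALSE),
      rmse = sqrt(mean(samples^2))
    ),
    class = "error_distribution"
  )
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "Error distribution: %d samples from %d trial(s); RMSE %.4g; quartiles %.4g / %.4g / %.4g\n",
    length(x$samples), x$trials, x$rmse,
    x$quartiles[1], x$quartiles[2], x$quartiles[3]
  ))
  invisible(x)
}

#' RMSE reduction factor
#'
#' Ratio of the default-radius RMSE to the optimized-radius RMSE.  Squared,
#' it gives the neuron-count reduction the optimization affords (see
#' [reduced_neuron_count()]).
#'
#' @param default_dist,optimized_dist [error_distribution()] objects.
#' @return Positive scalar factor.
#' @export
reduction_factor <- function(default_dist, optimized_dist) {
  stopifnot(
    inherits(default_dist, "error_distribution"),
    inherits(optimized_dist, "error_distribution")
  )
  if (optimized_dist$rmse <= 0) {
    stop("optimized RMSE is zero; reduction factor undefined", call. = FALSE)
  }
  default_dist$rmse / optimized_dist$rmse
}

#' Empirically measure the distortion of a subvector ensemble
#'
#' Rate-mode simulation of a single `m`-dimensional ensemble driven by the
#' first `m` components of a slowly varying `D`-dimensional unit signal.
#' Rate neurons carry no spiking noise, so after filtering the reference
#' identically (removing the synaptic delay), the mean squared difference
#' between decode and input is the distortion itself.
#'
#' @param N Neurons.
#' @param D Full signal dimensionality.
#' @param m Represented subvector dimensionality.
#' @param radius Ensemble radius.
#' @param gamma Regularization scale.
#' @param trials Number of independent signals.
#' @param seed Optional integer seed.
#' @param duration Trial duration in seconds.
#' @param dt Time step in seconds.
#' @param skip Initial transient to discard, in seconds.
#' @param synapse An [exp_synapse()] object.
#' @param params A [lif_params()] object.
#' @param per_trial Return the per-trial means instead of their average?
#' @return Mean squared Euclidean error (scalar, or a vector if
#'   `per_trial = TRUE`).
#' @export
measure_empirical_distortion <- function(N, D, m = 1, radius = 1,
                                         gamma = 0.1, trials = 5,
                                         seed = NULL, duration = 4,
                                         dt = 1e-3, skip = 0.5,
                                         synapse = exp_synapse(),
                                         params = lif_params(),
                                         per_trial = FALSE) {
  trials <- assert_count(trials, "trials")
  ens <- build_ensemble(N, m, radius, params, seed = seed)
  pts <- sample_eval_points(
    default_eval_count(N, m), m,
    radius = radius, seed = seed
  )
  dec <- static_distortion(ens, pts, gamma)$decoders$decoders
  sig_seeds <- derive_seeds(seed, trials)
  res <- vapply(seq_len(trials), function(tr) {
    sig <- generate_unit_signal(D, duration, dt, seed = sig_seeds[[tr]])
    X <- sig$samples[, seq_len(m), drop = FALSE]
    nt <- nrow(X)
    decoded <- matrix(0, nt, m)
    for (start in seq(1, nt, by = 2000L)) {
      it <- start:min(start + 1999L, nt)
      A <- activity_matrix(ens, X[it, , drop = FALSE])
      decoded[it, ] <- t(A) %*% dec
    }
    decoded <- filter_signal(decoded, synapse, dt)
    ref <- filter_signal(X, synapse, dt)
    keep <- sig$times > skip
    mean(rowSums((decoded - ref)[keep, , drop = FALSE]^2))
  }, numeric(1))
  if (per_trial) res else mean(res)
}

#' Analytic vs. empirical distortion across radii
#'
#' Tabulates the analytic error estimate [total_error()] against the
#' empirically measured rate-mode distortion over a grid of radii.  The
#' analytic column reuses a single unit-radius inside-distortion estimate
#' (same ensemble seed as the empirical runs, so the radius-scaling identity
#' is exact).
#'
#' @param N,D,m,gamma,trials,seed,duration,dt,skip,synapse,params As in
#'   [measure_empirical_distortion()].
#' @param radii Radius grid in `(0, 1]`.
#' @param empirical Include the empirical columns?
#' @return Data frame with columns `r`, `analytic`, and (if requested)
#'   `empirical`, `ci_low`, `ci_high` (95% normal interval over trials).
#' @export
distortion_curve <- function(N, D, m = 1, radii = seq(0.1, 1, by = 0.1),
                             gamma = 0.1, trials = 5, seed = NULL,
                             duration = 4, dt = 1e-3, skip = 0.5,
                             synapse = exp_synapse(),
                             params = lif_params(), empirical = TRUE) {
  stopifnot(all(radii > 0), all(radii <= 1))
  ens <- build_ensemble(N, m, 1, params, seed = seed)
  E1 <- distortion_inside_unit(ens, gamma = gamma)
  model <- distortion_model(E1, D, m)
  out <- data.frame(r = radii, analytic = total_error(radii, model))
  if (empirical) {
    emp <- lapply(radii, function(r) {
      measure_empirical_distortion(
        N, D, m, r, gamma, trials, seed, duration, dt, skip,
        synapse, params,
        per_trial = TRUE
      )
    })
    out$empirical <- vapply(emp, mean, numeric(1))
    se <- vapply(emp, function(e) stats::sd(e) / sqrt(length(e)), numeric(1))
    out$ci_low <- out$empirical - 1.96 * se
    out$ci_high <- out$empirical + 1.96 * se
  }
  out
}

#' Run a benchmark RMSE experiment
#'
#' Simulates one of the benchmark circuits under three conditions — default
#' radius, optimized radius, and optimized radius with the heuristically
#' reduced neuron count — over independent unit-signal trials, pooling the
#' per-time-step Euclidean errors against the exact (synapse-filtered)
#' algebraic reference.
#'
#' @param kind `"represent"`, `"convolve"`, or `"dot"`.
#' @param D Vector dimensionality.
#' @param neurons_per_dim Baseline neurons per scalar ensemble.
#' @param trials Number of independent trials.
#' @param duration Trial duration in seconds.
#' @param seed Optional integer seed.
#' @param mode `"spiking"` (default) or `"rate"`.
#' @param gamma,params,synapse,dt,skip Simulation parameters.
#' @param reduce Also run the reduced-neuron condition?
#' @return Object of class `nef_experiment`: config echo, the three
#'   [error_distribution()]s, `reduction_factor`, `reduced_N`.
#' @export
run_experiment <- function(kind = c("represent", "convolve", "dot"),
                           D, neurons_per_dim = 50, trials = 5,
                           duration = 4, seed = NULL,
                           mode = c("spiking", "rate"),
                           gamma = 0.1, params = lif_params(),
                           synapse = exp_synapse(), dt = 1e-3, skip = 0.5,
                           reduce = TRUE) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  trials <- assert_count(trials, "trials")
  sds <- derive_seeds(seed, 2 * trials + 1)
  sig_seeds <- sds[seq_len(trials)]
  sim_seeds <- sds[trials + seq_len(trials)]
  op_spec <- circuit_spec(kind, D, neurons_per_dim,
    radius_mode = "optimized",
    gamma = gamma, params = params, seed = seed
  )
  def_spec <- circuit_spec(kind, D, neurons_per_dim,
    radius_mode = "default",
    fixed_operand = op_spec$fixed_operand,
    gamma = gamma, params = params, seed = seed
  )
  signals <- lapply(sig_seeds, function(s) {
    generate_unit_signal(D, duration, dt, seed = s)
  })
  run_condition <- function(spec) {
    net <- build_circuit(spec)
    errs <- unlist(lapply(seq_len(trials), function(tr) {
      sim <- simulate_network(net, signals[[tr]],
        mode = mode,
        synapse = synapse, dt = dt, seed = sim_seeds[[tr]]
      )
      sim_errors(sim, skip = skip)
    }))
    error_distribution(errs, trials, duration, skip)
  }
  default_dist <- run_condition(def_spec)
  optimized_dist <- run_condition(op_spec)
  factor <- reduction_factor(default_dist, optimized_dist)
  floor_n <- if (kind == "dot") 5L else 1L
  reduced_dist <- NULL
  reduced_N <- NA_integer_
  if (reduce) {
    reduced_N <- reduced_neuron_count(
      neurons_per_dim, max(1, factor), floor_n
    )
    red_spec <- circuit_spec(kind, D, reduced_N,
      radius_mode = "optimized",
      fixed_operand = op_spec$fixed_operand,
      gamma = gamma, params = params, seed = seed
    )
    reduced_dist <- run_condition(red_spec)
  }
  structure(
    list(
      kind = kind, D = D, neurons_per_dim = neurons_per_dim,
      trials = trials, duration = duration, mode = mode, seed = seed,
      gamma = gamma, dt = dt, skip = skip,
      fixed_operand = op_spec$fixed_operand,
      default_dist = default_dist,
      optimized_dist = optimized_dist,
      reduced_dist = reduced_dist,
      reduction_factor = factor,
      reduced_N = reduced_N
    ),
    class = "nef_experiment"
  )
}

#' @export
print.nef_experiment <- function(x, ...) {
  cat(sprintf(
    paste0(
      "%s experiment, D = %d, %d neurons/dim, %d x %.3gs %s trials\n",
      "  RMSE default   %.4g\n  RMSE optimized %.4g  (reduction factor %.2f)\n"
    ),
    x$kind, x$D, x$neurons_per_dim, x$trials, x$duration, x$mode,
    x$default_dist$rmse, x$optimized_dist$rmse, x$reduction_factor
  ))
  if (!is.null(x$reduced_dist)) {
    cat(sprintf(
      "  RMSE reduced   %.4g  (%d neurons/dim)\n",
      x$reduced_dist$rmse, x$reduced_N
    ))
  }
  invisible(x)
}

#' Export an experiment report
#'
#' `write_experiment_json` writes the summary (config, RMSEs, quartiles,
#' reduction factor, reduced neuron count); `write_experiment_errors_csv`
#' writes the pooled per-step error samples, one column per condition.
#'
#' @param report A [run_experiment()] result.
#' @param path Output path.
#' @export
write_experiment_json <- function(report, path) {
  stopifnot(inherits(report, "nef_experiment"))
  summ <- function(d) {
    if (is.null(d)) {
      return(NULL)
    }
    list(rmse = d$rmse, quartiles = d$quartiles, n_samples = length(d$samples))
  }
  jsonlite::write_json(
    list(
      kind = report$kind, D = report$D,
      neurons_per_dim = report$neurons_per_dim,
      trials = report$trials, duration = report$duration,
      mode = report$mode, seed = report$seed, gamma = report$gamma,
      default = summ(report$default_dist),
      optimized = summ(report$optimized_dist),
      reduced = summ(report$reduced_dist),
      reduction_factor = report$reduction_factor,
      reduced_N = report$reduced_N
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_experiment_json
#' @export
write_experiment_errors_csv <- function(report, path) {
  stopifnot(inherits(report, "nef_experiment"))
  cols <- list(
    default = report$default_dist$samples,
    optimized = report$optimized_dist$samples
  )
  if (!is.null(report$reduced_dist)) {
    cols$reduced <- report$reduced_dist$samples
  }
  n <- max(vapply(cols, length, integer(1)))
  df <- as.data.frame(lapply(cols, function(x) c(x, rep(NA, n - length(x)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
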