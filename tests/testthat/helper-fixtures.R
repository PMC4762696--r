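# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Benchmark experiment at the scaled-down study size (5 trials x 4 s).
bench_experiment <- function(kind, D, seed = 42, trials = 5, duration = 4,
                             reduce = FALSE) {
  fixture(sprintf("exp_%s_%d_%d_%d", kind, D, seed, reduce), {
    run_experiment(kind, D = D, neurons_per_dim = 50, trials = trials,
                   duration = duration, seed = seed, reduce = reduce)
  })
}

# A sampled curve is unimodal if it never rises before its global minimum
# nor falls after it, up to numerical fluctuations below `tol`.
is_unimodal <- function(E, tol = 1e-6) {
  i <- which.min(E)
  all(diff(E[seq_len(i)]) < tol) && all(diff(E[i:length(E)]) > -tol)
}

# Decode mean squared error including the rate-noise term the regularization
# models (noise std gamma * max(A) per neuron); this is the error the
# 1/N neuron-reduction heuristic relies on.
noisy_decode_mse <- function(N, seed, gamma = 0.1) {
  ens <- build_ensemble(N, 1, seed = seed)
  pts <- sample_eval_points(default_eval_count(N, 1), 1, 1, seed = seed)
  A <- activity_matrix(ens, pts)
  dec <- solve_decoders(A, pts, gamma)
  resid <- pts - t(A) %*% dec$decoders
  mean(resid^2) + (gamma * max(A))^2 * sum(dec$decoders^2)
}
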