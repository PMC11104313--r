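# Shared fixtures: the reference reward configuration and small-run helpers.

spec_ref <- function(mu = 0.5, sigma = 0.2, skew = 0) moment_spec(mu, sigma, skew, 2.5)

run_stationary <- function(params = critic_params(), n_reps = 500,
                           n_trials = 100, seed = 1, spec = spec_ref(), ...) {
  run_replicates(stationary_env(spec), params, n_trials = n_trials,
                 n_reps = n_reps, seed = seed, ...)
}

# analytic beta moments, used as an independent oracle for the moment solver
beta_skew_exact <- function(a, b) 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
beta_kurt_exact <- function(a, b)
  3 + 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
    (a * b * (a + b + 2) * (a + b + 3))
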