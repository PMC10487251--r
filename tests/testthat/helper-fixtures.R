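# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# short-chain MCMC config for structural tests (not used for recovery checks)
quick_mcmc <- function() tac_mcmc(chains = 2, iterations = 900, burnin = 300,
                                  thin = 3, adapt = 300)

# the recovery experiment: 7 TP settings, 16 times x 4 replicates, sd 0.05
tp_recovery_fit <- function() cached("tp_fit", {
  des <- tac_design(replicates = 4, noise_sd = 0.05)
  study <- simulate_study(reference_curve_params("TP"), design = des,
                          seed = 42)
  fit_tac_bayes(study, marker = "TP", seed = 7)
})

# noiseless single-setting TP series on the default grid
noiseless_series <- function(theta, alpha1, alpha2, temperature = 180,
                             n_times = 16) {
  simulate_series(tac_params(theta, alpha1, alpha2), "synthA", "wheat",
                  temperature, design = tac_design(
                    times = seq(0, 1500, length.out = n_times),
                    noise_sd = 0))
}

# brute-force minimizer of the curve in the scaled coordinate x
grid_minimizer <- function(params, x_max = 50, step = 1e-3) {
  x <- seq(0, x_max, by = step)
  y <- params$theta + params$alpha1 * exp(-params$beta1 * x) +
    (params$alpha2 / 100) * exp(params$beta2 * x)
  x[which.min(y)]
}
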