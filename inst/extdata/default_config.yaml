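# Default run configuration: reproduces the synthetic seven-setting
# wheat/rye biscuit study with the built-in reference curve parameters.
seed: 1
markers: [TP, ORAC, FRAP]
scaling:
  exponent_scale: 7500     # divisor c in x = t*T/c
  response_scale: 1.0      # data already on the normalized scale
  overflow_cap: 50         # max allowed beta2 * x
design:
  n_times: 16              # equally spaced sampling times
  time_max: 1500           # s
  replicates: 2            # baking in duplicate
  noise_sd: 0.05           # normalized units
  heteroscedastic: false
priors:
  hyper_mean_loc: 1
  hyper_mean_scale: 1
  hyper_sd_scale: 1
  noise_sd_scale: 1
  hierarchy: global        # or: grain
mcmc:
  chains: 4
  iterations: 3000
  burnin: 1000
  thin: 3
  adapt: 1000
kernel:
  family: laplacian        # exponential kernel exp(-gamma * ||u - v||)
  cost_grid: [0.1, 1, 10, 100, 1000]
  epsilon: 0.01
  selection: training      # or: loo
rates:
  mode: default
  beta1: 0.08
  beta2: 0.12
sweep:
  variable: temperature    # 175-225 degC in 5 degC steps
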