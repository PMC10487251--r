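# tacbake

Kinetic modelling of **total antioxidant capacity (TAC)** in baked cereal
products. During baking, the antioxidant capacity of a wheat or rye biscuit
first falls, as thermolabile phenolics degrade, and later rises again as
Maillard reaction products (melanoidins) with their own antioxidant
activity accumulate. `tacbake` implements a two-level model of this
behaviour for three standard assays — total phenols (TP, mg GAE 100 g⁻¹
d.m.), peroxyl-radical scavenging (ORAC, µmol TE 100 g⁻¹ d.m.) and
ferric-reducing power (FRAP, µmol Fe²⁺ 100 g⁻¹ d.m.) — for food scientists
who want to predict how processing temperature and flour composition shape
the final antioxidant value of a product.

## The model

**Level 1 — kinetics.** The normalized response over baking time *t* (s)
and temperature *T* (°C) follows a double-exponential curve

  Ŷ(t, T) = θ + α₁·e^(−β₁·x) + (α₂/100)·e^(β₂·x),  x = t·T / c,

where θ is the baseline, α₁ the degradation amplitude, α₂ the formation
amplitude, and the rate constants are fixed at β₁ = 0.08, β₂ = 0.12.
The divisor c (default 7500) makes the exponent argument dimensionless on
a 0–1500 s, 175–225 °C domain. For each variety × temperature *setting*,
(θ, α₁, α₂) are estimated by a hierarchical Bayesian model (JAGS): a
Gaussian likelihood around the curve, setting-level parameters drawn from
shared truncated-Normal hyperpriors, chains initialized from
bound-constrained nonlinear least squares. Point estimates are posterior
medians.

**Level 2 — surrogate.** Support-vector regression with an exponential
(Laplacian) kernel, K(u,v) = exp(−γ‖u−v‖), regresses each curve parameter
on grain type (wheat/rye), protein, fiber and temperature, with the SVR
cost chosen by R² maximization. Composing the two levels predicts a full
TAC curve for unseen composition/temperature inputs, and one-at-a-time
sweeps (temperature 175–225 °C in 5 °C steps; protein and fiber ±20 %)
quantify local sensitivity.

Because the original bench measurements are not publicly deposited, the
package ships a seeded synthetic-data generator whose default truth is the
published seven-setting parameter table (`reference_curve_params()`), so
every claim is testable as a parameter-recovery experiment.

## Worked example

```r
library(tacbake)

# simulate the 7-setting TP study: 16 times x 4 replicates, noise sd 0.05
design <- tac_design(replicates = 4, noise_sd = 0.05)
study  <- simulate_study(reference_curve_params("TP"), design = design, seed = 42)

fit <- fit_tac_bayes(study, marker = "TP", seed = 7)
round(coef(fit), 3)
#>             theta alpha1 alpha2
#> Berdun 180  0.570  2.051  0.167
#> Igor 180    1.507  0.851  0.504
#> Teodor 180  1.396  0.364  0.986
#> Berdun 200  0.432  1.961  0.265
#> Loretto 200 1.730  0.916  0.995
#> Berdun 220  0.293  1.998  0.591
#> Loretto 220 1.444  1.055  2.531
```

Each row is one baking setting; the medians recover the generating values
(e.g. Berdun 180 °C truth: 0.605, 1.985, 0.100) within the noise-limited
uncertainty. Train the surrogate and sweep temperature:

```r
sur <- fit_tac_surrogate(fit, kernel = tac_kernel(epsilon = 0.001, cost_grid = 1000))
sw  <- sensitivity_sweep(sur, list(grain_type = "rye", protein = 10,
                                   fiber = 17.5, temperature = 200))
sw
#> Local sensitivity sweep of temperature (TP marker): 11 curves
#>   grid: 175, 180, 185, 190, 195, 200, 205, 210, 215, 220, 225
#>   value range at t = 1500 s: 4.6699; local slope: 0.09717 per unit temperature
sweep_spread(sw, 100)   # 0.52 — early times barely feel temperature
```

The spread of predicted values across temperatures at the end of baking
(4.67 normalized units) dwarfs the spread at 100 s (0.52): the process is
far more temperature-sensitive late in the bake, when formation dominates.

`turning_point()` gives the degradation-to-formation switch: for the
wheat 220 °C parameter set it falls at ≈ 929 s; at 180 °C it sits at the
edge of the 1500 s window (near-monotone decline).

A full simulate → fit → train → predict → sweep run, writing provenance-
stamped CSV/JSON at every stage, is one call:

```r
run_tac_pipeline(default_run_config(), seed = 1, out_dir = "run1")
```

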