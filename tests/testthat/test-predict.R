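interp_surrogate <- function() cached("interp_sur", {
  fit_tac_surrogate(tp_recovery_fit(),
                    kernel = tac_kernel(epsilon = 0.001, cost_grid = 1000))
})

test_that("predicted curves have one value per grid time, anchored at t = 0", {
  sur <- interp_surrogate()
  feats <- default_grain_features()[1, ]
  times <- seq(0, 1500, length.out = 16)
  cv <- predict_tac_curve(sur, feats$grain_type, feats$protein, feats$fiber,
                          200, times)
  expect_equal(nrow(cv), 16)
  p <- attr(cv, "params")
  expect_equal(cv$value[cv$time_s == 0],
               p$theta + p$alpha1 + p$alpha2 / 100)
  expect_error(predict_tac_curve(sur, "wheat", 12, 12, 200,
                                 times = numeric(0)), "non-empty")
})

test_that("end-to-end pipeline explains the noiseless truth curves", {
  sur <- interp_surrogate()
  truth <- reference_curve_params("TP")
  feats <- default_grain_features()
  times <- seq(0, 1500, length.out = 16)
  r2 <- sapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    f <- feats[feats$variety == tr$variety, ]
    cv <- suppressWarnings(predict_tac_curve(
      sur, f$grain_type, f$protein, f$fiber, tr$temperature_C, times))
    ref <- simulate_series(tac_params(tr$theta, tr$alpha1, tr$alpha2),
                           tr$variety, tr$grain_type, tr$temperature_C,
                           design = tac_design(noise_sd = 0))
    curve_r_squared(cv, ref)
  })
  expect_gte(sum(r2 >= 0.8), 5)
})

test_that("curve R-squared behaves algebraically", {
  p <- tac_params(0.6, 1.9, 0.5)
  times <- seq(0, 1500, length.out = 16)
  cv <- data.frame(time_s = times, value = evaluate_tac(p, times, 200))
  ref <- simulate_series(p, "v", "wheat", 200,
                         design = tac_design(noise_sd = 0, replicates = 1))
  expect_equal(curve_r_squared(cv, ref), 1)

  # shifting the reference by its own SD makes SS_res = SS_tot, so R2 = 0
  off <- ref
  off$value <- off$value + sd(off$value) * sqrt((16 - 1) / 16)
  expect_equal(curve_r_squared(cv, off), 0, tolerance = 1e-12)

  late <- ref[ref$time_s > 0, ]
  late$time_s <- late$time_s + 2000
  expect_error(curve_r_squared(cv, late), "overlap")
})

test_that("the default temperature sweep spans 11 curves", {
  sur <- interp_surrogate()
  base <- list(grain_type = "rye", protein = 10, fiber = 17.5,
               temperature = 200)
  sw <- sensitivity_sweep(sur, base)
  expect_length(sw$grid, 11)
  expect_equal(sw$grid, seq(175, 225, by = 5))
  expect_equal(nrow(sw$curves), 11 * 16)
  non_swept <- unique(sw$curves[, c("grain_type", "protein", "fiber")])
  expect_equal(nrow(non_swept), 1)  # frozen inputs identical across curves
  expect_error(sensitivity_sweep(sur, base, variable = "lysine"),
               "temperature, protein, fiber")
})

test_that("sensitivity grows with treatment time", {
  sur <- interp_surrogate()
  base <- list(grain_type = "rye", protein = 10, fiber = 17.5,
               temperature = 200)
  sw <- sensitivity_sweep(sur, base)
  expect_gt(sweep_spread(sw, 1500), sweep_spread(sw, 100))
})

test_that("a feature the surrogate never saw varying leaves curves flat", {
  # targets depend only on temperature; protein constant across training
  post <- tp_recovery_fit()$summary
  feats <- default_grain_features()
  feats$protein <- 12          # protein carries no signal
  ws <- capture_warnings(sur <- fit_tac_surrogate(post, feats))
  expect_match(ws, "zero-variance", all = TRUE)
  sw <- suppressWarnings(sensitivity_sweep(
    sur, list(grain_type = "rye", protein = 12, fiber = 17.5,
              temperature = 200), variable = "protein"))
  by_grid <- split(sw$curves$value, sw$curves$grid_value)
  for (v in by_grid[-1]) expect_equal(v, by_grid[[1]], tolerance = 1e-10)
})

test_that("late-time predictions increase with temperature past the minimum", {
  # forward model check driving the sweep behaviour
  p <- tac_params(0.309, 1.976, 0.566)
  temps <- seq(195, 225, 5)   # t*T/c at t = 1500 in [39, 45], past x* ~ 27
  finals <- evaluate_tac(p, 1500, temps)
  expect_true(all(diff(finals) > 0))
})
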