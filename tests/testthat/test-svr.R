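test_that("r_squared reproduces hand-computed cases exactly", {
  obs <- c(1, 2, 3)
  expect_identical(r_squared(obs, obs), 1)
  expect_identical(r_squared(obs, rep(2, 3)), 0)
  expect_identical(r_squared(obs, c(3, 2, 1)), 1 - 8 / 2)  # = -3
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_error(r_squared(1, 1), "at least 2")
})

test_that("r_squared is invariant to common affine rescaling", {
  set.seed(3)
  obs <- rnorm(20); pred <- obs + rnorm(20, 0, 0.3)
  r0 <- r_squared(obs, pred)
  expect_equal(r_squared(5 * obs - 2, 5 * pred - 2), r0)
})

test_that("training tables join posteriors with features per parameter", {
  fit <- tp_recovery_fit()
  tabs <- build_training_table(fit)
  expect_length(tabs, 3)       # theta, alpha1, alpha2 for one marker
  expect_true(all(vapply(tabs, nrow, 0L) == 7))
  expect_named(tabs[[1]], c("grain", "protein", "fiber", "temperature",
                            "target"))
  expect_true(all(tabs[[1]]$grain %in% c(0, 1)))

  feats <- default_grain_features()
  expect_error(build_training_table(fit, feats[feats$variety != "Loretto", ]),
               "Loretto")
})

test_that("SVR recovers a smooth target and selects cost deterministically", {
  set.seed(9)
  tab <- data.frame(grain = rep(c(0, 1), 10), protein = runif(20, 8, 16),
                    fiber = runif(20, 10, 20),
                    temperature = sample(c(180, 200, 220), 20, TRUE))
  tab$target <- 2 * tab$protein
  m <- train_svr(tab, tac_kernel())
  expect_gte(m$r2, 0.99)

  m2 <- train_svr(tab, tac_kernel())
  expect_identical(m$cost, m2$cost)
  expect_equal(m$r2, m2$r2)

  one <- train_svr(tab, tac_kernel(cost_grid = 7))
  expect_identical(one$cost, 7)

  const <- tab; const$target <- 1
  expect_error(train_svr(const, tac_kernel()), "untrainable")

  degen <- tab; degen$grain <- 0
  expect_warning(train_svr(degen, tac_kernel()), "zero-variance")
})

test_that("leave-one-out selection is available and bounded by 1", {
  fit <- tp_recovery_fit()
  tabs <- build_training_table(fit)
  m <- train_svr(tabs[[1]], tac_kernel(selection = "loo"))
  expect_lte(m$r2, 1)
})

test_that("near-interpolating surrogate reproduces training settings", {
  fit <- tp_recovery_fit()
  sur <- fit_tac_surrogate(fit, kernel = tac_kernel(epsilon = 0.001,
                                                    cost_grid = 1000))
  feats <- default_grain_features()
  cf <- coef(fit)
  for (i in c(1, 5, 7)) {
    tr <- reference_curve_params("TP")[i, ]
    f <- feats[feats$variety == tr$variety, ]
    p <- predict_params(sur, f$grain_type, f$protein, f$fiber,
                        tr$temperature_C, "TP")
    med <- cf[paste(tr$variety, tr$temperature_C), "theta"]
    expect_lt(abs(p$theta - med) / med, 0.05)
    expect_identical(p$beta1, 0.08)
    expect_identical(p$beta2, 0.12)
  }
})

test_that("predictions always satisfy the parameter invariants", {
  fit <- tp_recovery_fit()
  sur <- fit_tac_surrogate(fit)
  set.seed(14)
  for (i in 1:25) {
    p <- suppressWarnings(predict_params(
      sur, sample(c("wheat", "rye"), 1), runif(1, 6, 20), runif(1, 8, 24),
      runif(1, 170, 230), "TP"))
    expect_s3_class(p, "tac_params")
    expect_true(p$theta >= 0 && p$alpha1 >= 0 && p$alpha2 >= 0)
  }
})

test_that("out-of-range inputs trigger an extrapolation warning", {
  fit <- tp_recovery_fit()
  sur <- fit_tac_surrogate(fit)
  feats <- default_grain_features()
  expect_warning(predict_params(sur, "wheat", feats$protein[1],
                                feats$fiber[1], 300, "TP"),
                 "extrapolating")
})
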