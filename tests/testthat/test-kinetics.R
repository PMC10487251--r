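test_that("curve value at t = 0 is theta + alpha1 + alpha2/100", {
  p <- tac_params(0.605, 1.985, 0.100)
  expect_equal(evaluate_tac(p, 0, 180), 0.605 + 1.985 + 0.100 / 100)
  expect_equal(evaluate_tac(p, 0, 220), 2.591)  # independent of T at t = 0
})

test_that("curve collapses to the baseline when both amplitudes vanish", {
  p <- tac_params(1.3, 0, 0)
  expect_equal(evaluate_tac(p, c(0, 500, 1500), 200), rep(1.3, 3))
})

test_that("tiny rate constants give the constant-limit value", {
  p <- tac_params(0.5, 1.0, 2.0, beta1 = 1e-12, beta2 = 1e-12)
  expect_equal(evaluate_tac(p, 1500, 220), 0.5 + 1.0 + 2.0 / 100,
               tolerance = 1e-8)
})

test_that("invalid conditions and overflow are rejected", {
  p <- tac_params(1, 1, 1)
  expect_error(evaluate_tac(p, -5, 200), "non-negative")
  expect_error(evaluate_tac(p, 100, -200), "positive")
  expect_error(evaluate_tac(p, NA, 200), "finite")
  expect_error(evaluate_tac(p, 1500, 220, tac_scaling(exponent_scale = 1)),
               "overflow")
  expect_error(tac_params(-1, 1, 1), "non-negative")
  expect_error(tac_params(1, 1, 1, beta1 = 0), "positive")
})

test_that("closed-form minimizer matches brute-force grid search", {
  # wheat 220 degC parameter set: x* ~ 27.25
  p <- tac_params(0.309, 1.976, 0.566)
  x_star <- log(100 * p$alpha1 * p$beta1 / (p$alpha2 * p$beta2)) /
    (p$beta1 + p$beta2)
  expect_equal(x_star, 27.25, tolerance = 2e-4)
  expect_lt(abs(grid_minimizer(p) - x_star), 1e-2)

  set.seed(11)
  for (i in 1:100) {
    pr <- tac_params(runif(1, 0.1, 2), runif(1, 0.3, 2.5),
                     runif(1, 0.1, 2.5),
                     beta1 = runif(1, 0.05, 0.12),
                     beta2 = runif(1, 0.08, 0.2))
    tp <- turning_point(pr, 200)
    if (tp$x_star > 0 && tp$x_star < 50)
      expect_lt(abs(grid_minimizer(pr) - tp$x_star), 2e-3)
  }
})

test_that("turning point in seconds and window flags are correct", {
  sc <- tac_scaling()
  tp220 <- turning_point(tac_params(0.309, 1.976, 0.566), 220, sc)
  expect_equal(tp220$time_s, 929, tolerance = 1e-3)
  expect_identical(tp220$status, "interior")

  tp180 <- turning_point(tac_params(0.605, 1.985, 0.100), 180, sc)
  expect_equal(tp180$time_s, 1497, tolerance = 1e-3)
  expect_identical(tp180$status, "interior")  # just inside the window
  tp179 <- turning_point(tac_params(0.605, 1.985, 0.100), 179, sc)
  expect_identical(tp179$status, "out_of_window")

  expect_identical(turning_point(tac_params(1, 1, 0), 200)$status, "monotone")
  expect_identical(turning_point(tac_params(1, 0, 1), 200)$status, "monotone")
})

test_that("curve is decreasing before and increasing after the turning point", {
  p <- tac_params(0.309, 1.976, 0.566)
  x_star <- turning_point(p, 220)$x_star
  sc <- tac_scaling(exponent_scale = 1)   # evaluate directly in x
  x <- seq(0.01, 44, by = 0.01)
  y <- evaluate_tac(p, x, 1, sc)
  dy <- diff(y)
  expect_true(all(dy[x[-1] < x_star - 0.01] < 0))
  expect_true(all(dy[x[-length(x)] > x_star + 0.01] > 0))
})

test_that("past the turning point the response is non-decreasing in T", {
  p <- tac_params(0.309, 1.976, 0.566)
  temps <- seq(200, 225, by = 5)
  y <- evaluate_tac(p, 1500, temps)   # t*T/c in [40, 45], past x* ~ 27
  expect_true(all(diff(y) > 0))
})

test_that("normalization divides by the response scale and round-trips", {
  s <- noiseless_series(0.605, 1.985, 0.100)
  s$units <- "raw"; s$value <- s$value * 100
  sc <- tac_scaling(response_scale = 100)
  n <- normalize_response(s, sc)
  expect_identical(n$units[1], "normalized")
  expect_equal(n$value, s$value / 100)
  back <- denormalize_response(n, sc)
  expect_equal(back$value, s$value, tolerance = 1e-12)
  expect_error(tac_scaling(response_scale = 0), "positive")
})

test_that("grand-mean scale equals the average of the model curve", {
  s <- noiseless_series(0.605, 1.985, 0.100)
  mu <- evaluate_tac(tac_params(0.605, 1.985, 0.100),
                     seq(0, 1500, length.out = 16), 180)
  expect_equal(grand_mean_scale(s), mean(rep(mu, each = 2)))
})
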