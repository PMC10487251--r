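test_that("zero-noise simulation reproduces the model curve exactly", {
  p <- tac_params(1.0, 1.0, 1.0)
  des <- tac_design(noise_sd = 0)
  s <- simulate_series(p, "v", "wheat", 200, design = des)
  mu <- evaluate_tac(p, s$time_s, 200)
  expect_equal(s$value, mu)
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_study(design = tac_design(), seed = 99)
  b <- simulate_study(design = tac_design(), seed = 99)
  expect_identical(a, b)
  c <- simulate_study(design = tac_design(), seed = 100)
  expect_false(identical(a, c))
})

test_that("noise has the configured mean and spread (law of large numbers)", {
  p <- tac_params(1.0, 1.5, 0.8)
  des <- tac_design(times = 750, replicates = 10000, noise_sd = 0.05)
  set.seed(5)
  s <- simulate_series(p, "v", "rye", 200, design = des)
  mu <- evaluate_tac(p, 750, 200)
  expect_lt(abs(mean(s$value) - mu), 3 * 0.05 / sqrt(10000))
  expect_lt(abs(sd(s$value) - 0.05) / 0.05, 0.05)
})

test_that("the default study yields one series per setting and marker", {
  study <- simulate_study(design = tac_design(), seed = 1)
  combos <- unique(study[, c("variety", "temperature_C", "marker")])
  expect_equal(nrow(combos), 21)  # 7 settings x 3 markers
  expect_equal(nrow(study), 21 * 16 * 2)
  expect_true(all(study$time_s >= 0 & study$time_s <= 1500))
  expect_true(all(is.finite(study$value)))
})

test_that("single-setting designs and missing truth entries are handled", {
  one <- tac_design(settings = data.frame(variety = "Berdun",
                                          grain_type = "wheat",
                                          temperature_C = 180))
  expect_equal(nrow(unique(simulate_study(design = one,
                                          seed = 1)["marker"])), 3)
  odd <- tac_design(settings = data.frame(variety = "Nova",
                                          grain_type = "rye",
                                          temperature_C = 200))
  expect_error(simulate_study(design = odd, seed = 1), "Nova 200")
  dup <- data.frame(variety = c("Berdun", "Berdun"),
                    grain_type = "wheat", temperature_C = 180)
  expect_error(tac_design(settings = dup), "duplicated")
})

test_that("design validation rejects bad noise and empty grids", {
  expect_error(tac_design(noise_sd = -0.1), "non-negative")
  expect_error(tac_design(times = numeric(0)), "non-empty")
  expect_error(tac_design(replicates = 0), ">= 1")
})

test_that("generated series satisfy the series invariants by construction", {
  set.seed(21)
  for (i in 1:20) {
    des <- tac_design(times = sort(runif(sample(4:20, 1), 0, 1500)),
                      replicates = sample(1:4, 1),
                      noise_sd = runif(1, 0, 0.3))
    s <- simulate_series(tac_params(runif(1, 0, 2), runif(1, 0, 2),
                                    runif(1, 0, 2)),
                         "v", "wheat", sample(c(180, 200, 220), 1),
                         design = des)
    expect_silent(tacbake:::.check_series(s))
    expect_equal(nrow(s), length(des$times) * des$replicates)
  }
})

test_that("grain tables respect per-type uniform ranges", {
  g <- simulate_grain_table(5, seed = 2)
  expect_equal(nrow(g), 10)
  w <- g[g$grain_type == "wheat", ]
  r <- g[g$grain_type == "rye", ]
  expect_true(all(w$protein >= 10 & w$protein <= 16))
  expect_true(all(r$fiber >= 14 & r$fiber <= 20))

  big <- simulate_grain_table(10000, seed = 3)
  wp <- big$protein[big$grain_type == "wheat"]
  expect_lt(abs(min(wp) - 10) / 6, 0.01)  # order statistics approach bounds
  expect_lt(abs(max(wp) - 16) / 6, 0.01)

  degen <- simulate_grain_table(
    4, ranges = list(wheat = list(protein = c(12, 12), fiber = c(11, 11)),
                     rye = list(protein = c(9, 9), fiber = c(15, 15))),
    seed = 1)
  expect_equal(unique(degen$protein), c(12, 9))
  expect_error(
    simulate_grain_table(2, ranges = list(
      wheat = list(protein = c(16, 10), fiber = c(10, 15)))),
    "ordered")
})

test_that("heteroscedastic noise scales with the mean response", {
  p <- tac_params(2.0, 0, 0)   # constant curve, mean 2
  des <- tac_design(times = 100, replicates = 5000, noise_sd = 0.1,
                    heteroscedastic = TRUE)
  set.seed(8)
  s <- simulate_series(p, "v", "wheat", 200, design = des)
  expect_lt(abs(sd(s$value) - 0.2) / 0.2, 0.06)  # sd = 0.1 * mean
})
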