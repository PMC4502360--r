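test_that("bootstrap CI is degenerate at sigma = 0 and for one replicate", {
  ci0 <- bootstrap_ci(gain_risk_after(), sigmas = 0, n_replicates = 50,
                      seed = 1)
  expect_equal(ci0$optimal_time, 2300)
  expect_equal(ci0$lower_95, 2300)
  expect_equal(ci0$upper_95, 2300)

  ci1 <- bootstrap_ci(gain_risk_after(), sigmas = 120, n_replicates = 1,
                      n_trials = 30, seed = 2)
  expect_identical(ci1$lower_95, ci1$upper_95)
})

test_that("bootstrap CI brackets the optimum and narrows with more trials", {
  ci <- bootstrap_ci(gain_risk_after(), sigmas = c(0, 80, 160),
                     n_replicates = 500, seed = 3)
  expect_true(all(ci$lower_95 <= ci$optimal_time + 1e-9))
  expect_true(all(ci$upper_95 >= ci$optimal_time - 1e-9))
  wide <- ci$upper_95 - ci$lower_95
  expect_true(all(diff(wide) > 0))  # width grows with sigma
  ci_big <- bootstrap_ci(gain_risk_after(), sigmas = 160,
                         n_replicates = 500, n_trials = 400, seed = 3)
  expect_lt(ci_big$upper_95 - ci_big$lower_95, wide[3])
})

test_that("bootstrap CI is reproducible and substream-stable under grid subsetting", {
  a <- bootstrap_ci(gain_risk_after(), sigmas = c(50, 100), n_replicates = 200,
                    seed = 9)
  b <- bootstrap_ci(gain_risk_after(), sigmas = c(50, 100), n_replicates = 200,
                    seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_ci(gain_risk_after(), sigmas = -1), ">= 0")
})

test_that("distribution shifting finds the empirical optimum", {
  # point mass at 2200 moved exactly onto the risk_after peak
  e <- empirical_optimum(rep(2200, 25), gain_risk_after())
  expect_equal(e$optimal_shift, 100)
  expect_equal(e$optimal_mean_time, 2300)
  expect_equal(e$optimal_total_gain, 25 * 100)

  # exactly symmetric sample around 2300 under the tent gain: no shift helps
  sym <- 2300 + c(-180, -120, -60, 0, 60, 120, 180)
  expect_equal(empirical_optimum(sym, gain_no_risk())$optimal_shift, 0)

  # optimal total gain can never fall below the observed total
  withr::with_seed(5, {
    x <- rnorm(100, 2200, 120)
    e2 <- empirical_optimum(x, gain_risk_after())
    expect_gte(e2$optimal_total_gain, e2$observed_total_gain)
    expect_equal(e2$optimal_mean_time,
                 e2$observed_mean_time + e2$optimal_shift)
  })

  expect_error(empirical_optimum(numeric(0), gain_no_risk()), "empty")
  expect_error(empirical_optimum(2200, gain_no_risk()), "at least 2")
})

test_that("empirical optimum agrees with the model optimum on model samples", {
  # repeated simulated sessions at N(2146, 130^2): the shift-based optimum
  # should land near T*(risk_after, 130) on average
  tstar <- optimal_plan(gain_risk_after(), 130)$optimal_time
  ests <- withr::with_seed(17, {
    vapply(1:40, function(i) {
      empirical_optimum(rnorm(100, 2146, 130),
                        gain_risk_after())$optimal_mean_time
    }, numeric(1))
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - tstar), 3 * se + 5)
})

test_that("risk classification follows the CI geometry of each condition", {
  expect_equal(classify_strategy(2146, c(2000, 2060), "risk_after")$label,
               "risk_seeking")
  expect_equal(classify_strategy(1950, c(2000, 2060), "risk_after")$label,
               "risk_averse")
  expect_equal(classify_strategy(2030, c(2000, 2060), "risk_after")$label,
               "risk_neutral")
  # mirror condition: closer to the target means below the interval
  expect_equal(classify_strategy(2495, c(2540, 2680), "risk_before")$label,
               "risk_seeking")
  expect_equal(classify_strategy(2700, c(2540, 2680), "risk_before")$label,
               "risk_averse")
  # boundary values are inside the interval
  expect_equal(classify_strategy(2060, c(2000, 2060), "risk_after")$label,
               "risk_neutral")
  expect_error(classify_strategy(2300, c(2000, 2060), "no_risk"),
               "asymmetric")
})

test_that("classification looks up a bootstrap table by sigma", {
  ci <- bootstrap_ci(gain_risk_after(), sigmas = c(100, 101, 102),
                     n_replicates = 300, seed = 4)
  cl <- classify_strategy(2300, ci, "risk_after", sigma = 101)
  expect_equal(cl$label, "risk_seeking")  # target is far above T*(101)
  expect_equal(unname(cl$ci["lower"]), ci$lower_95[ci$sigma == 101])
  expect_error(classify_strategy(2300, ci, "risk_after", sigma = 250),
               "outside")
  expect_error(classify_strategy(2300, ci, "risk_after"), "required")
})
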