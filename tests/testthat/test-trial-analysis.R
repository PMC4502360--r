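test_that("outlier flagging implements the 2.5-SD rule", {
  x <- c(rep(2300, 99), 9999)
  expect_identical(which(flag_outliers(x)), 100L)
  expect_false(any(flag_outliers(rep(2300, 50))))  # SD = 0
  expect_error(flag_outliers(c(1, 2)), "at least 3")

  # expected flag count under Gaussian data ~ n P(|Z| > 2.5) (slightly
  # below, since sample mean/SD are estimated); never above ~5% of a session
  counts <- withr::with_seed(21, {
    vapply(1:300, function(i) sum(flag_outliers(rnorm(100, 2300, 100))),
           numeric(1))
  })
  expect_lt(abs(mean(counts) - 100 * 2 * pnorm(-2.5)), 0.35)
  expect_lt(mean(counts) / 100, 0.05)
})

test_that("trial scoring labels misses as zero-gain trials", {
  tab <- score_trials(c(2100, 2300, 2400), gain_risk_after())
  expect_equal(tab$gain, c(2100 / 23, 100, 0))
  expect_equal(tab$miss, c(FALSE, FALSE, TRUE))
  expect_identical(tab$miss, tab$gain == 0)

  tab_step <- score_trials(c(2285, 1800, 2700), gain_step())
  expect_equal(tab_step$gain, c(100, 0, 100))

  # no-risk sessions never miss in the plausible range
  withr::with_seed(8, {
    tab_nr <- score_trials(rnorm(100, 2300, 150), gain_no_risk())
    expect_false(any(tab_nr$miss))
  })
})

test_that("M statistic is the distance of the session mean from the target", {
  expect_equal(m_statistic(rep(2146.2, 10)), 153.8)
  expect_equal(m_statistic(rep(2494.5, 10)), 194.5)
  expect_equal(m_statistic(rep(2300, 10)), 0)
  expect_equal(m_statistic(c(100, 2146.2, 2146.2, 2146.2),
                           outlier = c(TRUE, FALSE, FALSE, FALSE)), 153.8)
  expect_error(m_statistic(c(2000, 2100), outlier = c(TRUE, TRUE)),
               "no non-outlier")
})

test_that("compensation table bins errors by M with the printed edge conventions", {
  # alternating sequence: every compensation is +-100, mirror bins oppose
  rt <- rep(c(2100, 2200), 10)
  ct <- compensation_table(rt, M = 60, convention = "exp1")
  expect_equal(ct$mean_compensation[2], 100)   # error -50 -> bin 2, next +100
  expect_equal(ct$mean_compensation[3], -100)  # error +50 -> bin 3, next -100
  expect_equal(sign(ct$mean_compensation[2]), -sign(ct$mean_compensation[3]))

  # edge membership: exp1 keeps +2M but drops -2M and 2.4M; exp2 mirrors
  M <- 100
  base <- rep(2300, 6)
  mk <- function(errs) c(2300 + errs, 2300)  # successor for every pair
  for (conv in c("exp1", "exp2")) {
    ct2 <- compensation_table(mk(c(240, -240)), M = M, convention = conv)
    expect_equal(sum(ct2$n_pairs), 0, info = conv)  # |2.4M| always excluded
  }
  ct_e1 <- compensation_table(mk(c(200, -200)), M = M, convention = "exp1")
  expect_equal(ct_e1$n_pairs, c(0L, 0L, 0L, 1L))  # +2M in bin 4, -2M dropped
  ct_e2 <- compensation_table(mk(c(200, -200)), M = M, convention = "exp2")
  expect_equal(ct_e2$n_pairs, c(1L, 0L, 0L, 0L))  # -2M in bin 1, +2M dropped

  expect_error(compensation_table(rt, M = 0), "> 0")
})

test_that("pairs spanning outliers are dropped and the final trial has no pair", {
  rt <- c(2100, 2200, 5000, 2150, 2250)
  tab <- data.frame(response_time_ms = rt,
                    outlier = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  ct <- compensation_table(tab, M = 500, convention = "exp1")
  # pairs (2,3) and (3,4) excluded; only (1,2) and (4,5) remain
  expect_equal(sum(ct$n_pairs), 2)
})

test_that("compensation regression recovers the lag-1 coefficient", {
  # generative lag-1 agent: comp_n = -(1+beta) (RT_n - plan) + eps, so the
  # slope of compensation on error is -(1+beta)
  beta <- 0.3
  slopes <- withr::with_seed(31, {
    vapply(1:60, function(i) {
      ag <- agent_spec(100, beta = beta)
      cfg <- session_config("no_risk")
      tab <- simulate_session(ag, cfg, seed = i)
      keep <- !tab$outlier & c(!tab$outlier[-1], FALSE)
      err <- tab$response_time_ms - mean(tab$response_time_ms[!tab$outlier])
      comp <- c(diff(tab$response_time_ms), NA)
      unname(coef(lm(comp[keep] ~ err[keep]))[2])
    }, numeric(1))
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-(1 + beta))), 3 * se)
})

test_that("split-half check finds no learning in stationary sessions and drift when present", {
  cfg <- session_config("no_risk")
  stationary <- withr::with_seed(41, {
    do.call(rbind, lapply(1:8, function(i)
      simulate_session(agent_spec(100), cfg, participant_id = sprintf("S%02d", i),
                       seed = i)))
  })
  sh <- split_half_check(stationary)
  expect_equal(nrow(sh$per_participant), 8)
  expect_gt(sh$across$p, 0.01)

  # +100 ms drift between halves is detected per participant
  drift <- withr::with_seed(43, {
    x <- c(rnorm(50, 2300, 100), rnorm(50, 2400, 100))
    score_trials(x, gain_no_risk(), participant_id = "D1")
  })
  shd <- split_half_check(drift)
  expect_lt(shd$per_participant$p, 0.05)
  expect_lt(shd$per_participant$mean_first, shd$per_participant$mean_last)

  # identical halves: t = 0 exactly
  flat <- score_trials(rep(2300, 100), gain_no_risk())
  expect_equal(split_half_check(flat)$per_participant$t, 0)

  # non-100-trial sessions split proportionally, with a warning
  odd <- score_trials(rnorm(60, 2300, 50), gain_no_risk())
  expect_warning(split_half_check(odd), "60 trials")
})

test_that("paired statistics match hand-computed values", {
  r <- paired_stats(c(2, 4, 6, 8), c(1, 2, 3, 4))
  # differences 1,2,3,4: t = 2.5 / (sd/sqrt(4)), sd = 1.29099
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.8730, tolerance = 1e-4)
  expect_equal(r$df, 3)
  expect_equal(r$cohen_d, 2.5 / sd(1:4), tolerance = 1e-12)

  ab <- paired_stats(c(1, 2, 3), c(1, 2, 3) + c(0.1, -0.2, 0.05))
  expect_equal(ab$df, 2)

  expect_error(paired_stats(1:3, 1:4), "equal length")
  expect_error(paired_stats(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("trial logs round-trip with metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- withr::with_seed(51, {
    simulate_session(agent_spec(120), session_config("risk_after"),
                     participant_id = "P07", seed = 3)
  })
  write_trial_log(tab, path, metadata = list(seed = 3, config_hash = "abc123"))
  back <- read_trial_log(path)
  expect_equal(back$response_time_ms, tab$response_time_ms)
  expect_equal(back$participant_id, tab$participant_id)
  expect_equal(attr(back, "metadata")$seed, "3")
  expect_equal(attr(back, "metadata")$config_hash, "abc123")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,condition,trial_index\nP1,no_risk,1", bad)
  expect_error(read_trial_log(bad), "response_time_ms")
})
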