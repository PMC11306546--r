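test_that("degenerate (all-certain) inputs collapse draws and CIs to the point", {
  g <- fixture_national()
  cfg <- sim_config(n_draws = 100, seed = 5)
  d <- draw_inputs(g, cfg)
  expect_true(all(d$chw_wage == 23.51))
  expect_true(all(d$oh_transportation == 0.651 * 43.65))
  est <- simulate_thresholds(g, config = cfg)
  expect_equal(est$ffs_ci_low, est$ffs_rate)
  expect_equal(est$ffs_ci_high, est$ffs_rate)
  expect_equal(est$pmpm_ci_low, est$pmpm_rate)
  # and the point equals the deterministic pipeline
  expect_equal(est$ffs_rate, point_thresholds(g)$ffs_rate)
})

test_that("draws are reproducible under a fixed seed and differ across seeds", {
  g <- make_geo("U-1", chw_sd = 3, rn_sd = 5,
                oh_sds = c(transportation = 8))
  cfg <- sim_config(n_draws = 500, seed = 42)
  e1 <- simulate_thresholds(g, config = cfg)
  e2 <- simulate_thresholds(g, config = cfg)
  expect_identical(e1, e2)
  e3 <- simulate_thresholds(g, config = sim_config(n_draws = 500, seed = 43))
  expect_false(identical(e1$ffs_rate, e3$ffs_rate))
})

test_that("sampled means converge to input means within Monte Carlo error", {
  g <- make_geo("U-2", chw = 23.51, chw_sd = 3)
  cfg <- sim_config(n_draws = 10000, seed = 7)
  set.seed(substream_seed(cfg$seed, 1))
  d <- draw_inputs(g, cfg)
  se <- 3 / sqrt(cfg$n_draws)
  expect_lt(abs(mean(d$chw_wage) - 23.51), 3 * se)
})

test_that("no sampled monetary input falls below the truncation floor", {
  # mean near zero with a large sd forces heavy resampling
  g <- make_geo("U-3", chw = 1, chw_sd = 3,
                oh = c(equipment = 0.5, software = 0.1, transportation = 2,
                       space = 0.2, benefits = 0.1),
                oh_sds = c(equipment = 2, transportation = 5))
  cfg <- sim_config(n_draws = 5000, seed = 9)
  set.seed(substream_seed(cfg$seed, 1))
  d <- draw_inputs(g, cfg)
  for (col in names(d)) expect_true(all(d[[col]] >= cfg$truncation_floor))
})

test_that("a linear wage-only model recovers the closed-form PMPM distribution", {
  # only the CHW wage uncertain: PMPM = (wage * 2080 + const) / (12 * 65),
  # so PMPM is normal with sd = 2 * 2080 / 780 = 5.333
  g <- make_geo("U-4", chw = 20, chw_sd = 2)
  cfg <- sim_config(n_draws = 10000, seed = 11)
  est <- simulate_thresholds(g, config = cfg)
  slope <- 2080 / (12 * 65)
  pmpm_sd <- 2 * slope
  expect_equal(sd(est$draws$pmpm), pmpm_sd, tolerance = 0.05)
  # empirical CI bounds approach the analytic normal quantiles
  q_se <- sqrt(0.975 * 0.025 / cfg$n_draws) / (dnorm(1.96) / pmpm_sd)
  expect_lt(abs((est$pmpm_ci_high - est$pmpm_ci_low) / 2 - 1.96 * pmpm_sd),
            3 * q_se)
})

test_that("doubling all monetary means with zero sds doubles point and CI bounds", {
  g <- fixture_national()
  g2 <- make_geo("U-5", chw = 2 * 23.51, rn = 2 * 39.88, msw = 2 * 29.37,
                 oh = 2 * fixture_national()$overhead$rates,
                 travel = g$travel_time_hours)
  cfg <- sim_config(n_draws = 50, seed = 3)
  suppressWarnings({
    e1 <- simulate_thresholds(g, config = cfg)
    e2 <- simulate_thresholds(g2, config = cfg)
  })
  expect_equal(e2$ffs_rate, 2 * e1$ffs_rate)
  expect_equal(e2$pmpm_ci_high, 2 * e1$pmpm_ci_high)
})

test_that("small draw counts at a 95% interval trigger a stability warning", {
  expect_warning(simulate_thresholds(fixture_national(),
                                     config = sim_config(n_draws = 20)),
                 "too small")
})

test_that("aggregate simulation reduces correctly in degenerate cases", {
  cfg <- sim_config(n_draws = 400, seed = 13)
  g <- make_geo("A-1", chw_sd = 2.5, oh_sds = c(transportation = 6))
  # a singleton aggregate is bit-identical to the per-geography estimate
  single <- simulate_thresholds(g, config = cfg)
  agg1 <- simulate_aggregate(list(g), config = cfg, label = g$geo_id)
  expect_identical(single$draws, agg1$draws)
  expect_equal(single$ffs_rate, agg1$ffs_rate)
  expect_equal(single$pmpm_ci_low, agg1$pmpm_ci_low)

  # two identical deterministic geographies aggregate to either alone
  d1 <- make_geo("D-1"); d2 <- make_geo("D-2")
  agg2 <- simulate_aggregate(list(d1, d2), config = cfg)
  expect_equal(agg2$ffs_rate, simulate_thresholds(d1, config = cfg)$ffs_rate)

  # disjoint deterministic costs average with a zero-width CI
  lo <- make_geo("D-3", chw = 10, rn = 20, msw = 20,
                 oh = c(equipment = 1, software = 1, transportation = 1,
                        space = 1, benefits = 1), travel = 0)
  hi <- make_geo("D-4", chw = 30, rn = 60, msw = 60,
                 oh = c(equipment = 3, software = 3, transportation = 3,
                        space = 3, benefits = 3), travel = 0)
  agg3 <- simulate_aggregate(list(lo, hi), config = cfg)
  mid <- (point_thresholds(lo)$pmpm_rate + point_thresholds(hi)$pmpm_rate) / 2
  expect_equal(agg3$pmpm_rate, mid)
  expect_equal(agg3$pmpm_ci_low, agg3$pmpm_ci_high)

  expect_error(simulate_aggregate(list(), config = cfg), "at least one")
  expect_error(simulate_aggregate(list(d1, d2), config = cfg, weights = c(0, 0)),
               "weights")
})

test_that("per-geography substreams make multi-geography runs order-stable", {
  cfg <- sim_config(n_draws = 300, seed = 17)
  set.seed(101)
  geos <- lapply(sprintf("O-%d", 1:4), random_geo, with_sds = TRUE)
  est_by_stream <- function(order) {
    vapply(seq_along(order), function(i) {
      simulate_thresholds(geos[[order[i]]], config = cfg,
                          stream = order[i])$ffs_rate
    }, numeric(1))[order(order)]
  }
  expect_equal(est_by_stream(1:4), est_by_stream(c(3, 1, 4, 2)))
})
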