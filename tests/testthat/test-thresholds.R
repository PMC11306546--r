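test_that("PMPM threshold spreads monthly cost over the panel", {
  expect_equal(round(pmpm_threshold(9111.70, 65), 2), 140.18)
  expect_equal(pmpm_threshold(6500, 65), 100)
  expect_equal(pmpm_threshold(1234.56, 1), 1234.56)
  expect_error(pmpm_threshold(100, 0), "panel_size")
  expect_error(pmpm_threshold(0, 65), "monthly_cost")
})

test_that("FFS threshold divides monthly cost by visit volume", {
  expect_equal(ffs_threshold(10000, 200), 50)
  expect_equal(round(ffs_threshold(9111.70, 171.14), 2), 53.24)
  expect_equal(ffs_threshold(777.77, 1), 777.77)
  expect_error(ffs_threshold(100, 0), "monthly_visits")
})

test_that("revenue at either threshold covers monthly cost exactly", {
  set.seed(41)
  for (i in 1:25) {
    cost <- runif(1, 2000, 30000)
    visits <- runif(1, 50, 400)
    panel <- sample(15:100, 1)
    expect_lt(abs(ffs_threshold(cost, visits) * visits - cost) / cost, 1e-12)
    expect_lt(abs(pmpm_threshold(cost, panel) * panel - cost) / cost, 1e-12)
  }
})

test_that("panel rescaling follows the inverse-panel law", {
  expect_equal(round(rescale_by_panel(140.18, 65, 100), 2), 91.12)
  expect_equal(round(rescale_by_panel(140.18, 65, 15), 2), 607.45)
  expect_equal(round(rescale_by_panel(53.24, 65, 100), 2), 34.61)
  expect_equal(rescale_by_panel(77.7, 65, 65), 77.7)
  # rate * panel is invariant under rescaling, and rates fall as panels grow
  set.seed(42)
  for (i in 1:20) {
    r <- runif(1, 20, 300); p0 <- runif(1, 10, 120); p1 <- runif(1, 10, 120)
    expect_equal(rescale_by_panel(r, p0, p1) * p1, r * p0)
    if (p1 > p0) expect_lt(rescale_by_panel(r, p0, p1), r)
  }
  expect_error(rescale_by_panel(-1, 65, 100), "> 0")
})

test_that("aggregation is a weighted mean with sane degenerate cases", {
  e40 <- threshold_estimate("A", 40, 40)
  e60 <- threshold_estimate("B", 60, 60)
  expect_equal(aggregate_estimates(list(e40, e60), label = "M")$ffs_rate, 50)
  expect_equal(aggregate_estimates(list(e40, e60), weights = c(1, 0))$ffs_rate, 40)
  expect_equal(aggregate_estimates(list(e60), weights = 3)$pmpm_rate, 60)
  # aggregate of identical estimates is that estimate
  agg <- aggregate_estimates(list(e40, e40, e40))
  expect_equal(agg$ffs_rate, 40)
  expect_equal(agg$pmpm_ci_high, 40)
  expect_error(aggregate_estimates(list(e40, e60), weights = 1), "length")
  expect_error(aggregate_estimates(list(e40, e60), weights = c(0, 0)), "weights")
  expect_error(aggregate_estimates(list()), "non-empty")
})

test_that("thresholds strictly increase in every cost component and FFS in travel", {
  set.seed(43)
  plan <- staffing_plan()
  svc <- service_model()
  for (i in 1:8) {
    geo <- random_geo(sprintf("M-%d", i))
    base <- point_thresholds(geo, plan, svc)
    bump <- runif(1, 0.5, 5)
    # CHW wage, supervisor wage, each overhead component
    for (field in c("chw", "rn", OVERHEAD_COMPONENTS)) {
      g2 <- geo
      if (field == "chw") g2$chw_wage$mean <- g2$chw_wage$mean + bump
      else if (field == "rn") g2$supervisor_wages$RN$mean <-
          g2$supervisor_wages$RN$mean + bump
      else {
        g2$overhead$rates[[field]] <- g2$overhead$rates[[field]] + bump
        g2$overhead$total <- sum(g2$overhead$rates)
      }
      up <- point_thresholds(g2, plan, svc)
      expect_gt(up$ffs_rate, base$ffs_rate)
      expect_gt(up$pmpm_rate, base$pmpm_rate)
    }
    # FFS rises with travel time; PMPM is travel-invariant
    g3 <- geo
    g3$travel_time_hours <- geo$travel_time_hours + 0.5
    up <- point_thresholds(g3, plan, svc)
    expect_gt(up$ffs_rate, base$ffs_rate)
    expect_equal(up$pmpm_rate, base$pmpm_rate)
  }
})

test_that("travel opportunity cost can move from capacity to the ledger", {
  g <- make_geo("T-OPP", travel = 0.8)
  plan <- staffing_plan()
  svc_cap <- service_model()
  svc_led <- service_model(travel_opportunity_in_overhead = TRUE)

  # ledger mode: capacity ignores travel, cost carries the wage value of it
  led <- point_thresholds(g, plan, svc_led)
  v0 <- monthly_visit_capacity(svc_cap, 0, plan)
  m0 <- total_cost(g, plan)$total_monthly
  m_led <- m0 + g$chw_wage$mean * 0.25 * 0.8 * v0
  expect_equal(led$ffs_rate, m_led / v0)
  expect_equal(led$pmpm_rate, m_led / 65)

  # with zero travel the two accountings coincide
  g0 <- make_geo("T-OPP0", travel = 0)
  expect_equal(point_thresholds(g0, plan, svc_led)$ffs_rate,
               point_thresholds(g0, plan, svc_cap)$ffs_rate)

  # PMPM responds to travel only in ledger mode; the hour is never charged twice
  cap <- point_thresholds(g, plan, svc_cap)
  expect_equal(cap$pmpm_rate, point_thresholds(g0, plan, svc_cap)$pmpm_rate)
  expect_gt(led$pmpm_rate, cap$pmpm_rate)

  # the break-even identity holds per draw in ledger mode too
  cfg <- sim_config(n_draws = 200, seed = 37)
  set.seed(substream_seed(cfg$seed, 1))
  d <- threshold_draws(make_geo("T-OPP2", chw_sd = 2, travel = 0.8),
                       plan, svc_led, cfg)
  expect_lt(max(abs(d$ffs * d$visits - d$monthly_cost) / d$monthly_cost), 1e-12)
})

test_that("threshold estimates enforce CI ordering and positivity", {
  expect_error(threshold_estimate("X", -1, 10), "finite and > 0")
  expect_error(threshold_estimate("X", 10, 10, ffs_ci_low = 11), "bracket")
  expect_error(threshold_estimate("X", 10, 10, pmpm_ci_high = 9), "bracket")
})
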