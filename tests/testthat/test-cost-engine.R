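plan_rn <- staffing_plan("RN")
plan_msw <- staffing_plan("MSW")

test_that("labor cost is wage times annual paid hours", {
  expect_equal(labor_cost(23.51, plan_rn), 48900.80)
  expect_equal(labor_cost(1.00, plan_rn), 2080.00)
  expect_equal(labor_cost(20.00, staffing_plan(annual_hours = 1040)), 20800.00)
  expect_error(labor_cost(0, plan_rn), "wage")
  expect_error(labor_cost(-5, plan_rn), "wage")
})

test_that("supervision cost allocates one shared supervisor across the team", {
  expect_equal(supervision_cost(39.88, plan_rn), 10368.80)
  expect_equal(supervision_cost(29.37, plan_msw), 10181.60)
  # a dedicated (1:1) supervisor costs their full annual wage
  expect_equal(supervision_cost(33.33, staffing_plan(supervisor_ratio = 1)),
               33.33 * 2080)
  expect_error(staffing_plan(supervisor_ratio = 0.5), "supervisor_ratio")
  expect_error(supervision_cost(-1, plan_rn), "wage")
})

test_that("overhead cost annualizes each component and preserves shares", {
  g <- fixture_national()
  oh <- overhead_cost(g$overhead, plan_rn)
  expect_equal(sum(oh), 43.65 * 2080)  # 90792
  expect_equal(unname(oh["transportation"] / sum(oh)), 0.651, tolerance = 1e-12)
  zero <- overhead_ledger(0, 0, 0, 0, 0)
  expect_true(all(overhead_cost(zero, plan_rn) == 0))
})

test_that("total cost composes labor, supervision and overhead additively", {
  g <- fixture_national()
  cb <- total_cost(g, plan_rn)
  expect_equal(cb$labor, 48900.80)
  expect_equal(cb$supervision, 10368.80)
  expect_equal(cb$total_annual, 150061.60)
  expect_equal(cb$total_monthly, 150061.60 / 12)

  # additivity holds to machine precision on random instances
  set.seed(31)
  for (i in 1:20) {
    geo <- random_geo(sprintf("C-%d", i))
    cb <- total_cost(geo, plan_rn)
    lhs <- cb$labor + cb$supervision + sum(cb$overhead_by_component)
    expect_lt(abs(lhs - cb$total_annual) / cb$total_annual, 1e-12)
    expect_equal(cb$total_monthly * 12, cb$total_annual)
  }
})

test_that("total cost is homogeneous of degree one in monetary inputs", {
  set.seed(32)
  for (i in 1:10) {
    geo <- random_geo(sprintf("H-%d", i))
    k <- runif(1, 0.5, 3)
    scaled <- make_geo(geo$geo_id,
                       chw = k * geo$chw_wage$mean,
                       rn = k * geo$supervisor_wages$RN$mean,
                       msw = k * geo$supervisor_wages$MSW$mean,
                       oh = k * geo$overhead$rates,
                       travel = geo$travel_time_hours)
    expect_equal(total_cost(scaled, plan_rn)$total_annual,
                 k * total_cost(geo, plan_rn)$total_annual)
  }
})

test_that("a degenerate all-zero ledger reduces total cost to labor", {
  g <- make_geo("Z-1", chw = 17, rn = 1e-9 + 16, oh = c(
    equipment = 0, software = 0, transportation = 0, space = 0, benefits = 0))
  g$supervisor_wages$RN$mean <- 16  # any supervisor; check labor dominance form
  cb <- total_cost(g, staffing_plan(supervisor_ratio = 1e9))
  expect_equal(cb$total_annual, 17 * 2080, tolerance = 1e-6)
})

test_that("total cost requires the plan's supervisor wage", {
  g <- fixture_national()
  g$supervisor_wages$MSW <- NULL
  expect_error(total_cost(g, plan_msw), "MSW")
})

test_that("monthly visit capacity matches the travel-burden formula", {
  svc <- service_model()
  expect_equal(monthly_visit_capacity(svc, 0, plan_rn), (2080 / 12) / 0.5)
  expect_equal(monthly_visit_capacity(svc, 0, plan_rn), 346.6667, tolerance = 1e-4)
  expect_equal(monthly_visit_capacity(svc, 0.8, plan_rn), (2080 / 12) / 0.7)
  expect_equal(monthly_visit_capacity(svc, 0.8, plan_rn), 247.619, tolerance = 1e-4)
  # all-in-person with travel equal to visit length halves zero-travel capacity
  svc_ip <- service_model(inperson_share = 1)
  expect_equal(monthly_visit_capacity(svc_ip, 0.5, plan_rn),
               monthly_visit_capacity(svc_ip, 0, plan_rn) / 2)
})

test_that("capacity is monotone in travel, in-person share and productivity", {
  set.seed(33)
  for (i in 1:15) {
    t1 <- runif(1, 0, 3); t2 <- t1 + runif(1, 0.1, 2)
    s1 <- runif(1, 0.05, 0.5); s2 <- s1 + runif(1, 0.05, 0.5)
    p1 <- runif(1, 0.3, 0.9); p2 <- min(1, p1 + runif(1, 0.05, 0.1))
    svc1 <- service_model(inperson_share = s1, productive_fraction = p1)
    expect_gt(monthly_visit_capacity(svc1, t1, plan_rn),
              monthly_visit_capacity(svc1, t2, plan_rn))
    expect_gt(monthly_visit_capacity(svc1, t1, plan_rn),
              monthly_visit_capacity(
                service_model(inperson_share = s2, productive_fraction = p1),
                t1, plan_rn))
    expect_lt(monthly_visit_capacity(svc1, t1, plan_rn),
              monthly_visit_capacity(
                service_model(inperson_share = s1, productive_fraction = p2),
                t1, plan_rn))
    # zero-travel identity: paid monthly hours * productivity / duration
    expect_equal(monthly_visit_capacity(svc1, 0, plan_rn),
                 2080 / 12 * p1 / 0.5)
  }
  expect_error(monthly_visit_capacity(service_model(), -1, plan_rn), "travel")
})
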