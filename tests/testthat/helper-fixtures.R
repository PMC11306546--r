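# compact builder for test geographies; all sds default to 0 (deterministic)
make_geo <- function(geo_id = "T-01", chw = 23.51, rn = 39.88, msw = 29.37,
                     chw_sd = 0, rn_sd = 0, msw_sd = 0,
                     oh = c(equipment = 4, software = 3, transportation = 28.42,
                            space = 4, benefits = 4.23),
                     oh_sds = NULL, travel = 0.8, metro = TRUE, weight = 1,
                     state = "TS") {
  geography_inputs(
    geo_id = geo_id, state = state, area_name = paste(geo_id, "area"),
    metro = metro,
    chw_wage = wage_dist(chw, chw_sd),
    supervisor_wages = list(RN = wage_dist(rn, rn_sd), MSW = wage_dist(msw, msw_sd)),
    overhead = overhead_ledger(oh[["equipment"]], oh[["software"]],
                               oh[["transportation"]], oh[["space"]],
                               oh[["benefits"]], sds = oh_sds),
    travel_time_hours = travel, employment_weight = weight
  )
}

# random valid geography for property-style tests (uses current RNG state)
random_geo <- function(geo_id = "R-01", with_sds = FALSE) {
  oh <- stats::runif(5, 0.5, 30)
  names(oh) <- c("equipment", "software", "transportation", "space", "benefits")
  make_geo(
    geo_id = geo_id,
    chw = stats::runif(1, 15, 35), rn = stats::runif(1, 20, 60),
    msw = stats::runif(1, 18, 45),
    chw_sd = if (with_sds) stats::runif(1, 0.5, 5) else 0,
    rn_sd = if (with_sds) stats::runif(1, 0.5, 8) else 0,
    msw_sd = if (with_sds) stats::runif(1, 0.5, 6) else 0,
    oh = oh,
    oh_sds = if (with_sds) stats::setNames(stats::runif(5, 0.1, 5), names(oh)),
    travel = stats::runif(1, 0, 3),
    metro = stats::runif(1) < 0.5
  )
}
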