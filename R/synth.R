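#' Synthetic geography-table configuration
#'
#' Targets for the synthetic input generator, chosen to emulate the
#' statistical structure of national wage-survey and overhead-survey data:
#' near-symmetric cross-geography wage variation (truncated normal),
#' strongly right-skewed overhead totals (log-normal), transportation
#' around 65% of overhead on average, and longer travel times in non-metro
#' areas.
#'
#' @param n_states Number of "states" to generate, default 52 (50 states
#'   plus DC and PR).
#' @param areas_per_state Sub-state areas per state, default 2 (one metro,
#'   one non-metro at the default `metro_fraction` of 0.5).
#' @param metro_fraction Fraction of areas flagged metro, in (0, 1).
#' @param chw_wage,rn_wage,msw_wage Lists with `mean` (national target),
#'   `geo_sd` (cross-geography sd of area means), `lo`/`hi` (truncation
#'   range) and `rel_sd` (within-geography sd as a fraction of the mean).
#' @param overhead List with `mean` (national target arithmetic mean per
#'   work-hour), `log_sd` (cross-geography log-scale sd), `rel_sd`
#'   (within-geography component sd fraction), `transport_share` (target
#'   mean share of overhead going to transportation, in (0,1)) and
#'   `share_conc` (beta concentration of the share across geographies).
#' @param travel List with `metro_mean`, `nonmetro_mean`, `sd` (hours of
#'   round-trip travel per in-person visit).
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(
    n_states = 52, areas_per_state = 2, metro_fraction = 0.5,
    chw_wage = list(mean = 23.51, geo_sd = 3.4, lo = 15.90, hi = 31.61, rel_sd = 0.25),
    rn_wage  = list(mean = 39.88, geo_sd = 9.0, lo = 17.96, hi = 64.10, rel_sd = 0.25),
    msw_wage = list(mean = 29.37, geo_sd = 5.5, lo = 16.22, hi = 42.49, rel_sd = 0.25),
    overhead = list(mean = 43.65, log_sd = 0.55, rel_sd = 0.40,
                    transport_share = 0.651, share_conc = 12),
    travel = list(metro_mean = 0.75, nonmetro_mean = 1.15, sd = 0.20),
    seed = 20230) {
  stopifnot(n_states >= 1, areas_per_state >= 1)
  if (metro_fraction <= 0 || metro_fraction >= 1) {
    stop("metro_fraction must be in (0, 1)", call. = FALSE)
  }
  for (w in list(chw_wage, rn_wage, msw_wage)) {
    stopifnot(w$mean > 0, w$geo_sd >= 0, w$lo < w$mean, w$mean < w$hi, w$rel_sd >= 0)
  }
  stopifnot(overhead$mean > 0, overhead$log_sd >= 0)
  if (overhead$transport_share <= 0 || overhead$transport_share >= 1) {
    stop("infeasible transport_share: must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_states = as.integer(n_states),
                 areas_per_state = as.integer(areas_per_state),
                 metro_fraction = metro_fraction,
                 chw_wage = chw_wage, rn_wage = rn_wage, msw_wage = msw_wage,
                 overhead = overhead, travel = travel, seed = as.integer(seed)),
            class = "synth_config")
}

# two-sided truncated normal by resampling
rnorm_range <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  repeat {
    bad <- which(x < lo | x > hi)
    if (length(bad) == 0L) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
}

#' Generate a synthetic geography input table
#'
#' Draws one geography per state-area cell: wage means from range-truncated
#' normals around the configured national targets, overhead totals from a
#' log-normal calibrated so its arithmetic mean equals the configured
#' national mean, a beta-distributed transportation share of overhead, the
#' remaining overhead split randomly over the other four components, and
#' travel times that are longer in non-metro areas. Within-geography sds
#' are attached as the configured fraction of each mean. Generation is
#' deterministic under the configuration seed.
#'
#' @param config A [synth_config].
#' @param path Optional CSV path; when given, the table is also written in
#'   the canonical input schema.
#' @return A named list of [geography_inputs].
#' @export
generate_geographies <- function(config = synth_config(), path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_states * config$areas_per_state
  state_codes <- sprintf("S%02d", rep(seq_len(config$n_states),
                                      each = config$areas_per_state))
  area_idx <- rep(seq_len(config$areas_per_state), times = config$n_states)
  metro <- stats::runif(n) < config$metro_fraction
  if (config$areas_per_state == 2L) {
    # with two areas per state mirror the OEWS layout: one metro, one non-metro
    metro <- area_idx == 1L
  }

  draw_wage <- function(w) rnorm_range(n, w$mean, w$geo_sd, w$lo, w$hi)
  chw_m <- draw_wage(config$chw_wage)
  rn_m <- draw_wage(config$rn_wage)
  msw_m <- draw_wage(config$msw_wage)

  oh <- config$overhead
  mu_log <- log(oh$mean) - oh$log_sd^2 / 2  # arithmetic mean = configured target
  oh_total <- stats::rlnorm(n, mu_log, oh$log_sd)
  sh <- oh$transport_share
  tr_share <- stats::rbeta(n, sh * oh$share_conc, (1 - sh) * oh$share_conc)
  # split the non-transport remainder over the other four components
  rest <- matrix(stats::rgamma(n * 4L, shape = 2), ncol = 4L)
  rest <- rest / rowSums(rest) * oh_total * (1 - tr_share)

  tt_mean <- ifelse(metro, config$travel$metro_mean, config$travel$nonmetro_mean)
  travel <- pmin(pmax(stats::rnorm(n, tt_mean, config$travel$sd), 0.05), 7.9)
  weight <- stats::rlnorm(n, 0, 0.5)  # employment weights, right-skewed

  geos <- vector("list", n)
  for (i in seq_len(n)) {
    geos[[i]] <- geography_inputs(
      geo_id = sprintf("%s-%s", state_codes[i], if (metro[i]) "M" else "N"),
      state = state_codes[i],
      area_name = sprintf("%s %s area", state_codes[i],
                          if (metro[i]) "metropolitan" else "nonmetropolitan"),
      metro = metro[i],
      chw_wage = wage_dist(chw_m[i], config$chw_wage$rel_sd * chw_m[i]),
      supervisor_wages = list(
        RN = wage_dist(rn_m[i], config$rn_wage$rel_sd * rn_m[i]),
        MSW = wage_dist(msw_m[i], config$msw_wage$rel_sd * msw_m[i])
      ),
      overhead = overhead_ledger(
        equipment = rest[i, 1], software = rest[i, 2],
        transportation = oh_total[i] * tr_share[i],
        space = rest[i, 3], benefits = rest[i, 4],
        sds = stats::setNames(
          oh$rel_sd * c(rest[i, 1], rest[i, 2], oh_total[i] * tr_share[i],
                        rest[i, 3], rest[i, 4]),
          OVERHEAD_COMPONENTS)
      ),
      travel_time_hours = travel[i],
      employment_weight = weight[i]
    )
  }
  names(geos) <- vapply(geos, `[[`, character(1), "geo_id")
  if (length(unique(names(geos))) != length(geos)) {
    # >2 areas per state can collide on the metro/non-metro suffix
    names(geos) <- sprintf("%s%02d", names(geos), seq_len(n))
    for (i in seq_len(n)) geos[[i]]$geo_id <- names(geos)[i]
  }
  if (!is.null(path)) write_geography_inputs(geos, path)
  geos
}

#' National composite fixture geography
#'
#' A single synthetic "national composite" geography carrying the national
#' mean inputs (CHW $23.51/h, RN $39.88/h, MSW $29.37/h, overhead $43.65
#' per work-hour with a 65.1% transportation share), with all sds zero, for
#' deterministic worked examples. The travel time is the calibrated
#' national mean of 0.95 h; it is a modelling assumption, not a survey
#' value.
#'
#' @return A [geography_inputs].
#' @examples
#' fixture_national()$chw_wage$mean  # 23.51
#' @export
fixture_national <- function() {
  transport <- 0.651 * 43.65
  rest <- (43.65 - transport) / 4
  geography_inputs(
    geo_id = "US-NATIONAL", state = "US",
    area_name = "Synthetic national composite", metro = TRUE,
    chw_wage = wage_dist(23.51),
    supervisor_wages = list(RN = wage_dist(39.88), MSW = wage_dist(29.37)),
    overhead = overhead_ledger(equipment = rest, software = rest,
                               transportation = transport, space = rest,
                               benefits = rest),
    travel_time_hours = 0.95, employment_weight = 1
  )
}
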