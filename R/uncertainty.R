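#' Monte Carlo simulation configuration
#'
#' Controls the uncertainty propagation: number of draws, master seed,
#' credible-interval level, and the truncation floor below which monetary
#' draws are resampled. The default 10,000 draws with a 95% percentile
#' interval follows standard probabilistic sensitivity analysis practice.
#'
#' @param n_draws Number of Monte Carlo draws (>= 1), default 10000.
#' @param seed Master integer seed; per-geography substreams are derived
#'   from it (see [substream_seed()]).
#' @param ci_level Credible-interval mass in (0, 1), default 0.95.
#' @param truncation_floor Dollar floor for sampled monetary inputs,
#'   default 0.01; negative or sub-floor normal draws are resampled, not
#'   clipped, to avoid point mass at the floor.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_draws = 10000, seed = 1, ci_level = 0.95,
                       truncation_floor = 0.01) {
  if (!is.numeric(n_draws) || n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 ci_level = as.numeric(ci_level),
                 truncation_floor = as.numeric(truncation_floor)),
            class = "sim_config")
}

#' Derive a per-geography substream seed from the master seed
#'
#' Deterministic seeding scheme: substream `i` gets
#' `(seed * 1000003 + i) mod (2^31 - 1)`. One master seed thus fixes every
#' geography's draw sequence independently of how many geographies run or
#' in what order, and the whole pipeline is reproducible bit-for-bit.
#'
#' @param seed Master integer seed.
#' @param i Substream index (1-based geography position).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i) %% (2^31 - 1))
}

# normal draws truncated below at `floor` by resampling (never clipping)
rnorm_trunc <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (iter in seq_len(1000L)) {
    bad <- which(x < floor)
    if (length(bad) == 0L) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  if (any(x < floor)) {
    stop("truncated sampling failed: distribution mass almost entirely below floor",
         call. = FALSE)
  }
  x
}

#' Sample uncertain inputs for one geography
#'
#' Each uncertain field (CHW wage, both supervisor wages, the five overhead
#' components) is replaced by an independent normal draw around its mean and
#' sd, truncated below at the configuration's floor by resampling. Fields
#' with sd = 0, and the travel time (no sd in the schema), pass through
#' unchanged. Fields are always sampled, in a fixed order, regardless of
#' which staffing plan will consume them, so scenario comparisons under the
#' same seed see identical draws.
#'
#' @param geo A [geography_inputs].
#' @param config A [sim_config].
#' @param n Number of draws (default `config$n_draws`).
#' @return A data.frame with `n` rows and columns `chw_wage`, `rn_wage`,
#'   `msw_wage`, `oh_equipment`, `oh_software`, `oh_transportation`,
#'   `oh_space`, `oh_benefits`. Uses the current RNG state; callers set the
#'   (substream) seed.
#' @export
draw_inputs <- function(geo, config, n = config$n_draws) {
  stopifnot(inherits(geo, "geography_inputs"), inherits(config, "sim_config"))
  fl <- config$truncation_floor
  rn <- geo$supervisor_wages$RN
  msw <- geo$supervisor_wages$MSW
  out <- data.frame(
    chw_wage = rnorm_trunc(n, geo$chw_wage$mean, geo$chw_wage$sd, fl),
    rn_wage = if (is.null(rn)) rep(NA_real_, n) else rnorm_trunc(n, rn$mean, rn$sd, fl),
    msw_wage = if (is.null(msw)) rep(NA_real_, n) else rnorm_trunc(n, msw$mean, msw$sd, fl)
  )
  for (k in OVERHEAD_COMPONENTS) {
    out[[paste0("oh_", k)]] <-
      rnorm_trunc(n, geo$overhead$rates[[k]], geo$overhead$sds[[k]], fl)
  }
  out
}

#' Per-draw cost and threshold engine for one geography
#'
#' Low-level vectorized core behind [simulate_thresholds()]: samples inputs
#' with [draw_inputs()] (using the current RNG state; callers seed) and
#' returns the per-draw monthly cost, the deterministic visit capacity, and
#' the per-draw break-even rates. Exposed so that the break-even identity
#' (`ffs * visits == monthly_cost`, `pmpm * panel == monthly_cost`) can be
#' audited draw by draw.
#'
#' @param geo A [geography_inputs].
#' @param plan A [staffing_plan].
#' @param svc A [service_model].
#' @param config A [sim_config].
#' @return A list of numeric vectors of length `n_draws`: `ffs`, `pmpm`,
#'   `monthly_cost`, plus the scalar `visits`.
#' @export
threshold_draws <- function(geo, plan = staffing_plan(), svc = service_model(),
                            config = sim_config()) {
  d <- draw_inputs(geo, config)
  H <- plan$annual_hours
  sup_wage <- switch(plan$supervisor_kind, RN = d$rn_wage, MSW = d$msw_wage)
  if (anyNA(sup_wage)) {
    stop("configuration error: no ", plan$supervisor_kind,
         " wage for geo ", geo$geo_id, call. = FALSE)
  }
  oh_total <- d$oh_equipment + d$oh_software + d$oh_transportation +
    d$oh_space + d$oh_benefits
  monthly_cost <- (d$chw_wage * H + sup_wage * H / plan$supervisor_ratio +
                     oh_total * H) / 12
  if (svc$travel_opportunity_in_overhead) {
    visits <- monthly_visit_capacity(svc, 0, plan)
    monthly_cost <- monthly_cost + d$chw_wage * svc$inperson_share *
      geo$travel_time_hours * visits
  } else {
    visits <- monthly_visit_capacity(svc, geo$travel_time_hours, plan)
  }
  list(ffs = ffs_threshold(monthly_cost, visits),
       pmpm = pmpm_threshold(monthly_cost, svc$panel_size),
       monthly_cost = monthly_cost, visits = visits)
}

# summarize per-draw ffs/pmpm vectors into a threshold_estimate
summarize_draws <- function(draws, config, label, state = NA_character_,
                            keep_draws = TRUE) {
  a <- (1 - config$ci_level) / 2
  qf <- stats::quantile(draws$ffs, c(a, 1 - a), type = 7, names = FALSE)
  qp <- stats::quantile(draws$pmpm, c(a, 1 - a), type = 7, names = FALSE)
  threshold_estimate(
    label = label, state = state,
    ffs_rate = mean(draws$ffs), ffs_ci_low = qf[1], ffs_ci_high = qf[2],
    pmpm_rate = mean(draws$pmpm), pmpm_ci_low = qp[1], pmpm_ci_high = qp[2],
    draws = if (keep_draws) list(ffs = draws$ffs, pmpm = draws$pmpm) else NULL,
    n_draws = length(draws$ffs)
  )
}

#' Monte Carlo threshold estimate for one geography
#'
#' Samples the uncertain inputs `n_draws` times (see [draw_inputs()]),
#' computes the break-even FFS and PMPM rates within every draw, and
#' summarizes: the point value is the mean of per-draw thresholds, the
#' credible interval the empirical percentile interval (2.5th and 97.5th at
#' the default 95% level). The break-even identity (rate times volume equals
#' monthly cost) holds within every draw.
#'
#' @param geo A [geography_inputs].
#' @param plan A [staffing_plan].
#' @param svc A [service_model].
#' @param config A [sim_config].
#' @param stream Substream index used to derive this geography's seed from
#'   the master seed (default 1).
#' @param keep_draws Keep the per-draw threshold vectors on the estimate
#'   (needed for per-draw panel rescaling and percentile grids)?
#' @return A [threshold_estimate].
#' @export
simulate_thresholds <- function(geo, plan = staffing_plan(), svc = service_model(),
                                config = sim_config(), stream = 1L,
                                keep_draws = TRUE) {
  if (config$n_draws < 40 && config$ci_level >= 0.95) {
    warning("n_draws = ", config$n_draws,
            " is too small for stable 95% percentile bounds", call. = FALSE)
  }
  set.seed(substream_seed(config$seed, stream))
  draws <- threshold_draws(geo, plan, svc, config)
  summarize_draws(draws, config, label = geo$geo_id, state = geo$state,
                  keep_draws = keep_draws)
}

#' Monte Carlo threshold estimate for a cross-geography aggregate
#'
#' Within each draw, computes the (weighted) mean threshold across all
#' geographies; the draw-level means are then summarized exactly as in
#' [simulate_thresholds()]. Each geography uses its own seed substream, so
#' the aggregate of a single geography reproduces that geography's estimate
#' bit-for-bit.
#'
#' @param geos Non-empty list of [geography_inputs].
#' @param plan A [staffing_plan].
#' @param svc A [service_model].
#' @param config A [sim_config].
#' @param weights Optional non-negative weights (default equal); all-zero
#'   weights are an error.
#' @param label Aggregate label, default "NATIONAL".
#' @param streams Substream indices, one per geography (default
#'   `seq_along(geos)`); lets a subset aggregate (e.g. METRO) reuse each
#'   geography's global substream so its draws match the full run.
#' @param keep_draws Keep per-draw aggregate thresholds on the estimate?
#' @return A [threshold_estimate].
#' @export
simulate_aggregate <- function(geos, plan = staffing_plan(), svc = service_model(),
                               config = sim_config(), weights = NULL,
                               label = "NATIONAL", streams = seq_along(geos),
                               keep_draws = TRUE) {
  n <- length(geos)
  if (n == 0L) stop("need at least one geography", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("length mismatch between geos and weights", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  stopifnot(length(streams) == n)
  w <- weights / sum(weights)
  ffs_acc <- numeric(config$n_draws)
  pmpm_acc <- numeric(config$n_draws)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, streams[i]))
    d <- threshold_draws(geos[[i]], plan, svc, config)
    ffs_acc <- ffs_acc + w[i] * d$ffs
    pmpm_acc <- pmpm_acc + w[i] * d$pmpm
  }
  summarize_draws(list(ffs = ffs_acc, pmpm = pmpm_acc), config, label = label,
                  keep_draws = keep_draws)
}
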