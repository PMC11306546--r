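#' Construct a threshold estimate
#'
#' Container for the two break-even payment outcomes of one geography or
#' aggregate: the minimum fee-for-service rate per 30-minute visit and the
#' minimum capitated per-member-per-month rate, each with a 95% credible
#' interval. In deterministic runs the CI bounds equal the point value.
#'
#' @param label Geography id or aggregate label ("NATIONAL", "METRO", ...).
#' @param ffs_rate,pmpm_rate Point values in dollars (> 0).
#' @param ffs_ci_low,ffs_ci_high,pmpm_ci_low,pmpm_ci_high CI bounds;
#'   default to the point values.
#' @param state Optional state code carried through to result tables.
#' @param draws Optional list with numeric vectors `ffs` and `pmpm`, the
#'   per-draw thresholds backing the summaries.
#' @param n_draws Number of Monte Carlo draws behind the estimate (1 for
#'   deterministic).
#' @return An object of class `threshold_estimate`.
#' @export
threshold_estimate <- function(label, ffs_rate, pmpm_rate,
                               ffs_ci_low = ffs_rate, ffs_ci_high = ffs_rate,
                               pmpm_ci_low = pmpm_rate, pmpm_ci_high = pmpm_rate,
                               state = NA_character_, draws = NULL, n_draws = 1L) {
  if (!is.finite(ffs_rate) || ffs_rate <= 0 || !is.finite(pmpm_rate) || pmpm_rate <= 0) {
    stop("threshold rates must be finite and > 0", call. = FALSE)
  }
  tol <- 1e-9 * max(1, ffs_rate, pmpm_rate)
  if (ffs_ci_low > ffs_rate + tol || ffs_ci_high < ffs_rate - tol ||
      pmpm_ci_low > pmpm_rate + tol || pmpm_ci_high < pmpm_rate - tol) {
    stop("CI bounds must bracket the point value", call. = FALSE)
  }
  structure(list(label = label, state = state,
                 ffs_rate = ffs_rate, ffs_ci_low = ffs_ci_low,
                 ffs_ci_high = ffs_ci_high,
                 pmpm_rate = pmpm_rate, pmpm_ci_low = pmpm_ci_low,
                 pmpm_ci_high = pmpm_ci_high,
                 draws = draws, n_draws = as.integer(n_draws)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %s\n", x$label))
  cat(sprintf("  FFS  $%.2f per 30-min visit (95%% CI %.2f, %.2f)\n",
              x$ffs_rate, x$ffs_ci_low, x$ffs_ci_high))
  cat(sprintf("  PMPM $%.2f per member-month (95%% CI %.2f, %.2f)  [%d draws]\n",
              x$pmpm_rate, x$pmpm_ci_low, x$pmpm_ci_high, x$n_draws))
  invisible(x)
}

# flatten a list of threshold_estimate into a results data.frame
estimates_to_df <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(label = e$label, state = e$state,
               ffs_rate = e$ffs_rate, ffs_ci_low = e$ffs_ci_low,
               ffs_ci_high = e$ffs_ci_high,
               pmpm_rate = e$pmpm_rate, pmpm_ci_low = e$pmpm_ci_low,
               pmpm_ci_high = e$pmpm_ci_high,
               n_draws = e$n_draws, stringsAsFactors = FALSE)
  }))
}

#' Break-even capitated rate per member per month
#'
#' The minimum PMPM payment at which panel revenue exactly covers the
#' monthly per-CHW cost: `monthly_cost / panel_size`.
#'
#' @param monthly_cost Dollars per CHW per month (> 0); vectorized.
#' @param panel_size Concurrent patients per CHW (>= 1).
#' @return Dollars per member per month.
#' @examples
#' pmpm_threshold(9111.70, 65)  # 140.18
#' @export
pmpm_threshold <- function(monthly_cost, panel_size) {
  if (!is.numeric(panel_size) || panel_size < 1) {
    stop("panel_size must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(monthly_cost) | monthly_cost <= 0)) {
    stop("monthly_cost must be finite and > 0", call. = FALSE)
  }
  monthly_cost / panel_size
}

#' Break-even fee-for-service rate per visit
#'
#' The minimum payment per 30-minute visit at which visit revenue exactly
#' covers the monthly per-CHW cost: `monthly_cost / monthly_visits`.
#'
#' @param monthly_cost Dollars per CHW per month (> 0); vectorized.
#' @param monthly_visits Visits delivered per month (> 0); vectorized.
#' @return Dollars per visit.
#' @examples
#' ffs_threshold(10000, 200)  # 50
#' @export
ffs_threshold <- function(monthly_cost, monthly_visits) {
  if (any(!is.finite(monthly_visits) | monthly_visits <= 0)) {
    stop("monthly_visits must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(monthly_cost) | monthly_cost <= 0)) {
    stop("monthly_cost must be finite and > 0", call. = FALSE)
  }
  monthly_cost / monthly_visits
}

#' Rescale a break-even rate to a different panel size
#'
#' Both thresholds scale inversely with panel size when the monthly per-CHW
#' cost is held fixed: PMPM because the cost is spread over more members,
#' FFS because visit volume is proportional to panel at fixed per-patient
#' visit intensity (demand-limited volume). Returns
#' `baseline_rate * baseline_panel / new_panel`.
#'
#' @param baseline_rate Rate in dollars at the reference panel (> 0);
#'   vectorized over draws.
#' @param baseline_panel Reference panel size (> 0).
#' @param new_panel Target panel size (> 0).
#' @return Rescaled rate in dollars.
#' @examples
#' rescale_by_panel(140.18, 65, 100)  # 91.12
#' rescale_by_panel(140.18, 65, 15)   # 607.45
#' @export
rescale_by_panel <- function(baseline_rate, baseline_panel, new_panel) {
  if (any(!is.finite(baseline_rate) | baseline_rate <= 0) ||
      baseline_panel <= 0 || new_panel <= 0) {
    stop("all arguments must be > 0", call. = FALSE)
  }
  baseline_rate * baseline_panel / new_panel
}

#' Aggregate threshold estimates across geographies
#'
#' Weighted arithmetic mean of point values and CI bounds. With the default
#' equal weights this is the unweighted cross-geography mean; employment
#' weights may be supplied instead. For aggregates with full uncertainty
#' propagation (mean-of-draws rather than mean-of-summaries) use
#' [simulate_aggregate()].
#'
#' @param estimates Non-empty list of [threshold_estimate].
#' @param weights Non-negative weights, one per estimate, not all zero;
#'   default equal.
#' @param label Label for the aggregate row.
#' @return A [threshold_estimate].
#' @export
aggregate_estimates <- function(estimates, weights = NULL, label = "AGGREGATE") {
  n <- length(estimates)
  if (n == 0L) stop("estimates must be non-empty", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) {
    stop("length mismatch: ", n, " estimates vs ", length(weights), " weights",
         call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  w <- weights / sum(weights)
  pick <- function(field) sum(w * vapply(estimates, `[[`, numeric(1), field))
  threshold_estimate(
    label = label,
    ffs_rate = pick("ffs_rate"), pmpm_rate = pick("pmpm_rate"),
    ffs_ci_low = pick("ffs_ci_low"), ffs_ci_high = pick("ffs_ci_high"),
    pmpm_ci_low = pick("pmpm_ci_low"), pmpm_ci_high = pick("pmpm_ci_high"),
    n_draws = max(vapply(estimates, `[[`, integer(1), "n_draws"))
  )
}

#' Deterministic thresholds for one geography
#'
#' Point-value pipeline without Monte Carlo: total cost at input means,
#' capacity from the service model and travel time, then both break-even
#' rates. Warns when demand-implied visit volume (panel times per-patient
#' visit intensity) exceeds capacity.
#'
#' @param geo A [geography_inputs].
#' @param plan A [staffing_plan].
#' @param svc A [service_model].
#' @return A [threshold_estimate] with CI bounds equal to the point values.
#' @export
point_thresholds <- function(geo, plan = staffing_plan(), svc = service_model()) {
  cb <- total_cost(geo, plan)
  monthly <- cb$total_monthly
  if (svc$travel_opportunity_in_overhead) {
    visits <- monthly_visit_capacity(svc, 0, plan)
    monthly <- monthly + geo$chw_wage$mean * svc$inperson_share *
      geo$travel_time_hours * visits
  } else {
    visits <- monthly_visit_capacity(svc, geo$travel_time_hours, plan)
  }
  threshold_estimate(
    label = geo$geo_id, state = geo$state,
    ffs_rate = ffs_threshold(monthly, visits),
    pmpm_rate = pmpm_threshold(monthly, svc$panel_size)
  )
}
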