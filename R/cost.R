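#' Staffing plan for a CHW team
#'
#' Supervision structure and paid hours. The base case uses a Registered
#' Nurse care manager shared across 8 CHWs; the sensitivity scenario a
#' Master's-level social worker shared across 6. A full-time CHW works 2080
#' paid hours per year.
#'
#' @param supervisor_kind "RN" or "MSW".
#' @param supervisor_ratio CHWs per supervisor; defaults to 8 for RN and 6
#'   for MSW; must be >= 1.
#' @param annual_hours Paid hours per CHW per year (> 0), default 2080.
#' @return An object of class `staffing_plan`.
#' @examples
#' staffing_plan()            # RN, 1:8, 2080 h
#' staffing_plan("MSW")       # MSW, 1:6
#' @export
staffing_plan <- function(supervisor_kind = c("RN", "MSW"),
                          supervisor_ratio = NULL, annual_hours = 2080) {
  supervisor_kind <- match.arg(supervisor_kind)
  if (is.null(supervisor_ratio)) {
    supervisor_ratio <- switch(supervisor_kind, RN = 8, MSW = 6)
  }
  if (!is.numeric(supervisor_ratio) || supervisor_ratio < 1) {
    stop("supervisor_ratio must be >= 1", call. = FALSE)
  }
  if (!is.numeric(annual_hours) || annual_hours <= 0) {
    stop("annual_hours must be > 0", call. = FALSE)
  }
  structure(list(supervisor_kind = supervisor_kind,
                 supervisor_ratio = as.numeric(supervisor_ratio),
                 annual_hours = as.numeric(annual_hours)),
            class = "staffing_plan")
}

#' Service delivery model
#'
#' Panel and visit parameters: 65 concurrent patients per CHW enrolled for a
#' mean of 6 months, 30-minute visits, and a 1:3 in-person-to-virtual visit
#' mix (in-person share 0.25). `productive_fraction` is the fraction of paid
#' hours available for visits plus travel; the default of 1 is the most
#' generous (lowest-threshold) assumption, with no administrative deduction.
#'
#' @param panel_size Concurrent patients per CHW (>= 1), default 65.
#' @param enrollment_months Mean service duration per patient, default 6.
#'   Affects reporting (patients served per year) only, not revenue, because
#'   PMPM is billed per concurrent member-month.
#' @param visit_duration Visit length in hours (> 0), default 0.5.
#' @param inperson_share Fraction of visits delivered in person, in (0, 1],
#'   default 0.25.
#' @param productive_fraction Fraction of paid hours bookable for visits and
#'   travel, in (0, 1], default 1.
#' @param travel_opportunity_in_overhead How the wage value of travel time is
#'   realized. `FALSE` (default): solely through reduced visit capacity, with
#'   the transportation ledger covering vehicle and commute dollars only.
#'   `TRUE`: capacity ignores travel and the CHW wage cost of travel hours is
#'   charged to the monthly cost instead. Never both — that would charge the
#'   same hour twice.
#' @return An object of class `service_model`.
#' @export
service_model <- function(panel_size = 65, enrollment_months = 6,
                          visit_duration = 0.5, inperson_share = 0.25,
                          productive_fraction = 1,
                          travel_opportunity_in_overhead = FALSE) {
  if (!is.numeric(panel_size) || panel_size < 1) {
    stop("panel_size must be >= 1", call. = FALSE)
  }
  if (!is.numeric(visit_duration) || visit_duration <= 0) {
    stop("visit_duration must be > 0", call. = FALSE)
  }
  if (!is.numeric(inperson_share) || inperson_share <= 0 || inperson_share > 1) {
    stop("inperson_share must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(productive_fraction) || productive_fraction <= 0 ||
      productive_fraction > 1) {
    stop("productive_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(enrollment_months) || enrollment_months <= 0) {
    stop("enrollment_months must be > 0", call. = FALSE)
  }
  structure(list(panel_size = as.numeric(panel_size),
                 enrollment_months = as.numeric(enrollment_months),
                 visit_duration = as.numeric(visit_duration),
                 inperson_share = as.numeric(inperson_share),
                 productive_fraction = as.numeric(productive_fraction),
                 travel_opportunity_in_overhead =
                   isTRUE(travel_opportunity_in_overhead)),
            class = "service_model")
}

#' Annual labor cost of one CHW
#'
#' @param wage CHW hourly wage in dollars (> 0); vectorized over draws.
#' @param plan A [staffing_plan].
#' @return Dollars per year: `wage * annual_hours`.
#' @examples
#' labor_cost(23.51, staffing_plan())  # 48900.80
#' @export
labor_cost <- function(wage, plan) {
  if (any(!is.finite(wage) | wage <= 0)) {
    stop("wage must be finite and > 0", call. = FALSE)
  }
  wage * plan$annual_hours
}

#' Annual per-CHW supervision cost
#'
#' One supervisor is shared across `supervisor_ratio` CHWs, so each CHW
#' carries `sup_wage * annual_hours / supervisor_ratio` of supervisor wage.
#'
#' @param sup_wage Supervisor hourly wage in dollars (> 0); vectorized.
#' @param plan A [staffing_plan].
#' @return Dollars per year allocated to one CHW.
#' @examples
#' supervision_cost(39.88, staffing_plan())  # 10368.80
#' @export
supervision_cost <- function(sup_wage, plan) {
  if (any(!is.finite(sup_wage) | sup_wage <= 0)) {
    stop("supervisor wage must be finite and > 0", call. = FALSE)
  }
  if (plan$supervisor_ratio < 1) stop("supervisor_ratio must be >= 1", call. = FALSE)
  sup_wage * plan$annual_hours / plan$supervisor_ratio
}

#' Annual overhead cost by component
#'
#' Converts the per-work-hour overhead ledger to annual dollars per CHW:
#' each component rate times annual paid hours.
#'
#' @param ledger An [overhead_ledger].
#' @param plan A [staffing_plan].
#' @return Named numeric vector of five annual components, in dollars.
#' @export
overhead_cost <- function(ledger, plan) {
  stopifnot(inherits(ledger, "overhead_ledger"))
  ledger$rates * plan$annual_hours
}

#' Total annual and monthly cost of supporting one CHW
#'
#' Sums labor, ratio-allocated supervision and the five overhead components
#' into a per-CHW cost breakdown. Supervision is wage allocation only:
#' supervisor-attributable overhead is assumed folded into the per-CHW-hour
#' overhead ledger.
#'
#' @param geo A [geography_inputs].
#' @param plan A [staffing_plan]; the supervisor wage for
#'   `plan$supervisor_kind` must be present in `geo`.
#' @return An object of class `cost_breakdown`: `labor`, `supervision`,
#'   `overhead_by_component` (all dollars/year), `total_annual`,
#'   `total_monthly`.
#' @examples
#' g <- fixture_national()
#' total_cost(g, staffing_plan())  # total_annual 150061.60
#' @export
total_cost <- function(geo, plan) {
  stopifnot(inherits(geo, "geography_inputs"), inherits(plan, "staffing_plan"))
  sup <- geo$supervisor_wages[[plan$supervisor_kind]]
  if (is.null(sup)) {
    stop("configuration error: no ", plan$supervisor_kind,
         " wage for geo ", geo$geo_id, call. = FALSE)
  }
  labor <- labor_cost(geo$chw_wage$mean, plan)
  supervision <- supervision_cost(sup$mean, plan)
  oh <- overhead_cost(geo$overhead, plan)
  total <- labor + supervision + sum(oh)
  structure(list(labor = labor, supervision = supervision,
                 overhead_by_component = oh,
                 total_annual = total, total_monthly = total / 12),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> per CHW, 2023 USD\n")
  cat(sprintf("  labor        %12.2f /yr\n", x$labor))
  cat(sprintf("  supervision  %12.2f /yr\n", x$supervision))
  for (k in names(x$overhead_by_component)) {
    cat(sprintf("  %-12s %12.2f /yr\n", k, x$overhead_by_component[[k]]))
  }
  cat(sprintf("  total        %12.2f /yr = %.2f /month\n",
              x$total_annual, x$total_monthly))
  invisible(x)
}

#' Monthly visit capacity of one CHW
#'
#' Visits a CHW can deliver per month once in-person travel is accounted
#' for. Each visit costs `visit_duration` hours; an in-person visit (an
#' `inperson_share` fraction of all visits) additionally carries the full
#' round-trip `travel_time`; virtual visits carry none. Capacity is the
#' bookable monthly hours divided by the expected hours per visit:
#' `(annual_hours/12 * productive_fraction) /
#'  (visit_duration + inperson_share * travel_time)`.
#' Fractional visits are kept unrounded: the capacity is a rate, not a
#' schedule.
#'
#' @param svc A [service_model].
#' @param travel_time Round-trip travel hours per in-person visit (>= 0);
#'   vectorized over draws.
#' @param plan A [staffing_plan].
#' @return Visits per month (numeric, possibly fractional).
#' @examples
#' monthly_visit_capacity(service_model(), 0, staffing_plan())    # 346.67
#' monthly_visit_capacity(service_model(), 0.8, staffing_plan())  # 247.62
#' @export
monthly_visit_capacity <- function(svc, travel_time, plan) {
  stopifnot(inherits(svc, "service_model"), inherits(plan, "staffing_plan"))
  if (any(!is.finite(travel_time) | travel_time < 0)) {
    stop("travel_time must be finite and >= 0", call. = FALSE)
  }
  denom <- svc$visit_duration + svc$inperson_share * travel_time
  if (any(denom <= 0)) {
    stop("visit_duration + inperson_share * travel_time must be > 0",
         call. = FALSE)
  }
  (plan$annual_hours / 12 * svc$productive_fraction) / denom
}
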