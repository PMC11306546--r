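#' Wage distribution for one occupation in one geography
#'
#' Hourly wage summarized as a mean and standard deviation, the form in which
#' the BLS OEWS survey reports occupation wages by area. The Monte Carlo
#' engine samples from a normal distribution with these moments; `sd = 0`
#' marks the wage as certain.
#'
#' @param mean Mean hourly wage in dollars; must be > 0.
#' @param sd Standard deviation of the hourly wage in dollars; must be >= 0.
#' @return An object of class `wage_dist` with fields `mean` and `sd`.
#' @examples
#' wage_dist(23.51, 2.5)
#' @export
wage_dist <- function(mean, sd = 0) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0) {
    stop("wage mean must be finite and > 0, got ", mean, call. = FALSE)
  }
  if (!is.finite(sd) || sd < 0) {
    stop("wage sd must be finite and >= 0, got ", sd, call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "wage_dist")
}

#' Overhead expenditure ledger for one geography
#'
#' The five non-wage cost categories per CHW work-hour: equipment (phone,
#' laptop, IT support), software (care management, telehealth, billing),
#' transportation (fuel, maintenance, insurance, depreciation), office space,
#' and employee benefits. All rates are dollars per hour of CHW paid work.
#' Each component may carry an optional standard deviation for uncertainty
#' propagation; a missing sd is treated as 0 (certain).
#'
#' @param equipment,software,transportation,space,benefits Dollar cost per
#'   CHW work-hour for each category; each must be finite and >= 0.
#' @param sds Optional named numeric vector of per-component standard
#'   deviations (names among the component names); unnamed components get 0.
#' @return An object of class `overhead_ledger` with fields `rates` (named
#'   numeric, the five components), `sds` (named numeric) and `total`.
#' @examples
#' overhead_ledger(4, 3, 28.42, 4, 4.23)
#' @export
overhead_ledger <- function(equipment, software, transportation, space, benefits,
                            sds = NULL) {
  rates <- c(equipment = equipment, software = software,
             transportation = transportation, space = space, benefits = benefits)
  rates <- vapply(rates, as.numeric, numeric(1))
  bad <- !is.finite(rates) | rates < 0
  if (any(bad)) {
    stop("overhead components must be finite and >= 0; offending: ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)
  }
  sd_full <- stats::setNames(numeric(length(OVERHEAD_COMPONENTS)), OVERHEAD_COMPONENTS)
  if (!is.null(sds)) {
    if (is.null(names(sds)) || !all(names(sds) %in% OVERHEAD_COMPONENTS)) {
      stop("overhead sds must be named by component", call. = FALSE)
    }
    if (any(!is.finite(sds) | sds < 0)) {
      stop("overhead sds must be finite and >= 0", call. = FALSE)
    }
    sd_full[names(sds)] <- as.numeric(sds)
  }
  structure(list(rates = rates, sds = sd_full, total = sum(rates)),
            class = "overhead_ledger")
}

#' Input bundle for one simulation geography
#'
#' One state or sub-state metropolitan/non-metropolitan area: CHW and
#' supervisor wage distributions, the overhead ledger, round-trip travel time
#' per in-person visit, a metro flag, and an optional employment weight used
#' in cross-geography aggregation.
#'
#' @param geo_id Unique string identifier for the geography.
#' @param state Two-letter state code (plus DC, PR).
#' @param area_name Human-readable area name.
#' @param metro Logical; TRUE for metropolitan statistical areas.
#' @param chw_wage A [wage_dist] for community health workers.
#' @param supervisor_wages Named list of [wage_dist] objects for supervisor
#'   occupations; names among "RN" and "MSW".
#' @param overhead An [overhead_ledger].
#' @param travel_time_hours Round-trip travel time in hours attached to each
#'   in-person visit; must satisfy 0 <= t < 8.
#' @param employment_weight Non-negative aggregation weight (default 1).
#' @return An object of class `geography_inputs`.
#' @examples
#' geography_inputs("US-00", "US", "National composite", TRUE,
#'   chw_wage = wage_dist(23.51), supervisor_wages = list(RN = wage_dist(39.88)),
#'   overhead = overhead_ledger(4, 3, 28.42, 4, 4.23), travel_time_hours = 0.8)
#' @export
geography_inputs <- function(geo_id, state, area_name, metro,
                             chw_wage, supervisor_wages, overhead,
                             travel_time_hours, employment_weight = 1) {
  stopifnot(is.character(geo_id), length(geo_id) == 1L, nzchar(geo_id))
  stopifnot(is.character(state), length(state) == 1L)
  stopifnot(inherits(chw_wage, "wage_dist"), inherits(overhead, "overhead_ledger"))
  if (!is.list(supervisor_wages) || is.null(names(supervisor_wages)) ||
      !all(names(supervisor_wages) %in% c("RN", "MSW")) ||
      !all(vapply(supervisor_wages, inherits, logical(1), "wage_dist"))) {
    stop("supervisor_wages must be a named list of wage_dist objects (RN, MSW)",
         call. = FALSE)
  }
  travel_time_hours <- as.numeric(travel_time_hours)
  if (!is.finite(travel_time_hours) || travel_time_hours < 0 || travel_time_hours >= 8) {
    stop("geo ", geo_id, ": travel_time_hours must satisfy 0 <= t < 8, got ",
         travel_time_hours, call. = FALSE)
  }
  employment_weight <- as.numeric(employment_weight)
  if (!is.finite(employment_weight) || employment_weight < 0) {
    stop("geo ", geo_id, ": employment_weight must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(geo_id = geo_id, state = state, area_name = area_name,
                 metro = isTRUE(metro), chw_wage = chw_wage,
                 supervisor_wages = supervisor_wages, overhead = overhead,
                 travel_time_hours = travel_time_hours,
                 employment_weight = employment_weight),
            class = "geography_inputs")
}

#' @export
print.geography_inputs <- function(x, ...) {
  cat(sprintf("<geography_inputs> %s (%s, %s)\n", x$geo_id, x$state,
              if (x$metro) "metro" else "non-metro"))
  cat(sprintf("  CHW wage $%.2f/h (sd %.2f); overhead $%.2f/h; travel %.2f h/visit\n",
              x$chw_wage$mean, x$chw_wage$sd, x$overhead$total, x$travel_time_hours))
  invisible(x)
}

#' Adjust a dollar amount to 2023 US dollars
#'
#' Applies a Consumer Price Index multiplier mapping source-year dollars to
#' the common 2023 dollar-year used throughout the model. The factor is a
#' user input because source streams (wage surveys, overhead surveys) carry
#' different base years.
#'
#' @param amount Dollar amount (finite numeric, vectorized).
#' @param cpi_factor Unitless multiplier, > 0.
#' @return `amount * cpi_factor`.
#' @examples
#' adjust_to_2023_usd(100, 1.05)
#' @export
adjust_to_2023_usd <- function(amount, cpi_factor) {
  if (!is.numeric(cpi_factor) || length(cpi_factor) != 1L ||
      !is.finite(cpi_factor) || cpi_factor <= 0) {
    stop("cpi_factor must be a single finite value > 0", call. = FALSE)
  }
  if (any(!is.finite(amount))) stop("amount must be finite", call. = FALSE)
  amount * cpi_factor
}
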