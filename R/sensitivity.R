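#' Supervisor substitution analysis
#'
#' Runs the full Monte Carlo pipeline twice over the same geographies and
#' the same seed, differing only in the staffing plan: a Registered Nurse
#' care manager shared 1:8 versus a Master's-level social worker shared 1:6
#' by default. Because every uncertain field is sampled in a fixed order
#' under per-geography substreams, the two scenarios see identical input
#' draws and any difference in the estimates is purely structural. Only the
#' supervision wage and ratio change; the overhead ledger is left untouched.
#'
#' @param geos Non-empty list of [geography_inputs]; every geography must
#'   carry wages for both supervisor occupations.
#' @param svc A [service_model].
#' @param config A [sim_config].
#' @param plan_a,plan_b The two staffing plans compared; default RN 1:8 vs
#'   MSW 1:6.
#' @param weights Optional aggregation weights.
#' @param label Aggregate label, default "NATIONAL".
#' @return A list with elements named after the two supervisor kinds, each a
#'   [threshold_estimate] for the aggregate.
#' @export
supervisor_swap <- function(geos, svc = service_model(), config = sim_config(),
                            plan_a = staffing_plan("RN"),
                            plan_b = staffing_plan("MSW"),
                            weights = NULL, label = "NATIONAL") {
  missing_b <- vapply(geos, function(g) {
    is.null(g$supervisor_wages[[plan_b$supervisor_kind]])
  }, logical(1))
  if (any(missing_b)) {
    stop("configuration error: geographies missing ", plan_b$supervisor_kind,
         " wages: ",
         paste(vapply(geos[missing_b], `[[`, character(1), "geo_id"),
               collapse = ", "),
         call. = FALSE)
  }
  res <- list(
    simulate_aggregate(geos, plan_a, svc, config, weights, label),
    simulate_aggregate(geos, plan_b, svc, config, weights, label)
  )
  stats::setNames(res, c(plan_a$supervisor_kind, plan_b$supervisor_kind))
}

#' Panel-size sensitivity sweep
#'
#' Rescales a baseline threshold estimate (computed at a reference panel,
#' 65 by default) across a grid of panel sizes, from small panels of 15 to
#' large panels of 100. The inverse-panel rescaling is applied to the point
#' value and to every stored draw, so the credible-interval bounds rescale
#' by exactly the same factor as the point value. A sweep point at the
#' reference panel returns the baseline unchanged.
#'
#' @param baseline A [threshold_estimate] computed at `baseline_panel`.
#' @param panels Numeric vector of panel sizes (> 0); default grid
#'   `c(15, 25, 35, 45, 55, 65, 75, 85, 100)`.
#' @param baseline_panel Reference panel size behind `baseline`, default 65.
#' @param scenario Label for the sweep.
#' @return An object of class `panel_sweep`: list with `scenario`,
#'   `baseline_panel`, `panels` (sorted increasing) and `estimates` (one
#'   [threshold_estimate] per panel). `as.data.frame()` gives the flat table.
#' @export
panel_sweep <- function(baseline, panels = c(15, 25, 35, 45, 55, 65, 75, 85, 100),
                        baseline_panel = 65, scenario = "panel_sweep") {
  stopifnot(inherits(baseline, "threshold_estimate"))
  if (any(!is.finite(panels) | panels <= 0)) {
    stop("panel sizes must be finite and > 0", call. = FALSE)
  }
  panels <- sort(unique(panels))
  if (any(panels > baseline_panel)) {
    warning("panels above the reference (",
            paste(panels[panels > baseline_panel], collapse = ", "),
            "): demand-implied visit volume exceeds baseline capacity; ",
            "FFS assumes demand-limited volume", call. = FALSE)
  }
  estimates <- lapply(panels, function(p) {
    f <- baseline_panel / p
    draws <- if (!is.null(baseline$draws)) {
      list(ffs = baseline$draws$ffs * f, pmpm = baseline$draws$pmpm * f)
    }
    threshold_estimate(
      label = sprintf("%s@panel=%g", baseline$label, p), state = baseline$state,
      ffs_rate = baseline$ffs_rate * f,
      ffs_ci_low = baseline$ffs_ci_low * f, ffs_ci_high = baseline$ffs_ci_high * f,
      pmpm_rate = baseline$pmpm_rate * f,
      pmpm_ci_low = baseline$pmpm_ci_low * f, pmpm_ci_high = baseline$pmpm_ci_high * f,
      draws = draws, n_draws = baseline$n_draws
    )
  })
  structure(list(scenario = scenario, baseline_panel = baseline_panel,
                 panels = panels, estimates = estimates),
            class = "panel_sweep")
}

#' @export
as.data.frame.panel_sweep <- function(x, ...) {
  df <- estimates_to_df(x$estimates)
  cbind(data.frame(scenario = x$scenario, panel_size = x$panels), df)
}

#' @export
print.panel_sweep <- function(x, ...) {
  cat(sprintf("<panel_sweep> '%s', reference panel %g\n", x$scenario,
              x$baseline_panel))
  df <- as.data.frame(x)
  print(df[, c("panel_size", "ffs_rate", "pmpm_rate")], row.names = FALSE)
  invisible(x)
}
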