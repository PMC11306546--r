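#' Run the full threshold pipeline over an input table
#'
#' End-to-end driver: loads (or accepts) a geography table, runs the Monte
#' Carlo threshold simulation per geography, builds state, metro/non-metro
#' and national aggregates, and writes a results CSV, a JSON variant with
#' percentile grids, and a run manifest sufficient to reproduce the outputs
#' bit-for-bit. Outputs are fully determined by (inputs, config, seed).
#'
#' @param inputs Path to an input CSV in the canonical schema, or a list of
#'   [geography_inputs].
#' @param out_dir Directory for results files (created if needed).
#' @param plan A [staffing_plan].
#' @param svc A [service_model].
#' @param config A [sim_config].
#' @param use_weights Use employment weights in aggregation (default FALSE:
#'   unweighted means across geographies)?
#' @param verbose Log progress to stderr?
#' @return Invisibly, a list with `estimates` (per-geography), `aggregates`
#'   (state + NATIONAL/METRO/NONMETRO), and the file paths written.
#' @export
run_pipeline <- function(inputs, out_dir = "results",
                         plan = staffing_plan(), svc = service_model(),
                         config = sim_config(), use_weights = FALSE,
                         verbose = TRUE) {
  t0 <- Sys.time()
  log_msg <- function(...) if (verbose) message(sprintf(...))
  input_path <- NULL
  if (is.character(inputs)) {
    input_path <- inputs
    geos <- load_geography_inputs(inputs)
  } else {
    geos <- inputs
  }
  if (length(geos) == 0L) stop("no geographies to simulate", call. = FALSE)
  log_msg("loaded %d geographies; %d draws, seed %d",
          length(geos), config$n_draws, config$seed)

  w <- if (use_weights) {
    vapply(geos, `[[`, numeric(1), "employment_weight")
  } else rep(1, length(geos))

  estimates <- vector("list", length(geos))
  for (i in seq_along(geos)) {
    estimates[[i]] <- simulate_thresholds(geos[[i]], plan, svc, config,
                                          stream = i, keep_draws = FALSE)
  }
  names(estimates) <- names(geos)

  states <- vapply(geos, `[[`, character(1), "state")
  metro <- vapply(geos, `[[`, logical(1), "metro")
  aggregates <- list()
  for (s in unique(states)) {
    idx <- which(states == s)
    agg <- simulate_aggregate(geos[idx], plan, svc, config, weights = w[idx],
                              label = s, streams = idx, keep_draws = FALSE)
    agg$state <- s
    aggregates[[s]] <- agg
  }
  for (grp in list(list("NATIONAL", seq_along(geos)),
                   list("METRO", which(metro)),
                   list("NONMETRO", which(!metro)))) {
    idx <- grp[[2]]
    if (length(idx) == 0L) next
    aggregates[[grp[[1]]]] <-
      simulate_aggregate(geos[idx], plan, svc, config, weights = w[idx],
                         label = grp[[1]], streams = idx, keep_draws = FALSE)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "thresholds.csv")
  json_path <- file.path(out_dir, "thresholds.json")
  manifest_path <- file.path(out_dir, "manifest.json")
  all_est <- c(estimates, aggregates)
  write_results(all_est, csv_path)
  write_results_json(all_est, json_path)
  write_run_manifest(manifest_path, input_path = input_path,
                     n_geos = length(geos), plan = plan, svc = svc,
                     config = config, use_weights = use_weights)
  log_msg("wrote %s (%d rows) in %.1f s", csv_path, length(all_est),
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(estimates = estimates, aggregates = aggregates,
                 paths = c(csv = csv_path, json = json_path,
                           manifest = manifest_path)))
}

#' Run manifest
#'
#' Writes a JSON manifest pairing a results file with everything needed to
#' reproduce it: configuration snapshot, input checksum, seed, package
#' version and timestamp.
#'
#' @param path Manifest output path.
#' @param input_path Input CSV path (md5-checksummed) or NULL for in-memory
#'   inputs.
#' @param n_geos Number of geographies simulated.
#' @param plan,svc,config The run configuration objects.
#' @param use_weights Whether employment weights were used.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, input_path, n_geos, plan, svc, config,
                               use_weights) {
  manifest <- list(
    package = "chwpay",
    version = as.character(utils::packageVersion("chwpay")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input = list(
      path = if (is.null(input_path)) NA else input_path,
      md5 = if (is.null(input_path)) NA else unname(tools::md5sum(input_path)),
      n_geographies = n_geos
    ),
    staffing = unclass(plan),
    service = unclass(svc),
    simulation = unclass(config),
    use_weights = use_weights
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Render a results table as Markdown
#'
#' Human-readable summary mirroring the published table layout: one row per
#' geography or aggregate with the FFS mean and 95% CI and the PMPM mean
#' and 95% CI, currency to cents. Rows are sorted by label so rendering is
#' order-stable under input permutation.
#'
#' @param results Non-empty list of [threshold_estimate], or the list
#'   returned by [run_pipeline()].
#' @return A character vector of Markdown lines (invisibly printable with
#'   `cat(x, sep = "\n")`).
#' @export
render_report <- function(results) {
  if (!is.null(results$estimates)) {
    results <- c(results$estimates, results$aggregates)
  }
  if (length(results) == 0L) stop("results must be non-empty", call. = FALSE)
  df <- estimates_to_df(results)
  df <- df[order(df$label), , drop = FALSE]
  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(
    "| Geography | FFS per visit | FFS 95% CI | PMPM | PMPM 95% CI |",
    "|---|---|---|---|---|",
    sprintf("| %s | $%s | (%s, %s) | $%s | (%s, %s) |",
            df$label, fmt(df$ffs_rate), fmt(df$ffs_ci_low), fmt(df$ffs_ci_high),
            fmt(df$pmpm_rate), fmt(df$pmpm_ci_low), fmt(df$pmpm_ci_high))
  )
  lines
}
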