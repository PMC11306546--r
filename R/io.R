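# CSV schema for geography input tables. Version "1" is the fixed documented
# header; the oh_*_sd columns are optional (within-geography overhead sds) and
# default to 0 when absent. Any other extra column is ignored with a warning.
GEO_SCHEMA_REQUIRED <- c(
  "geo_id", "state", "area_name", "metro",
  "chw_wage_mean", "chw_wage_sd",
  "rn_wage_mean", "rn_wage_sd",
  "msw_wage_mean", "msw_wage_sd",
  "oh_equipment", "oh_software", "oh_transportation", "oh_space", "oh_benefits",
  "travel_time_hours", "employment_weight"
)
GEO_SCHEMA_OPTIONAL <- paste0("oh_", OVERHEAD_COMPONENTS, "_sd")

#' Load a geography input table from CSV
#'
#' Reads a UTF-8 CSV with the documented column schema into a list of
#' validated [geography_inputs] objects. Validation is total: every row
#' either yields a valid object or raises an error naming the geography and
#' field; rows are never silently dropped. Missing optional sd columns
#' default to 0 (certain); unknown extra columns are ignored with a warning.
#'
#' @param path Path to the CSV file.
#' @param schema_version Schema version string; only "1" is defined.
#' @return A named list of [geography_inputs], one per row, names = geo_id.
#' @seealso [write_geography_inputs()] for the inverse operation.
#' @export
load_geography_inputs <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown schema_version '", schema_version, "'; only \"1\" is defined",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(geo_id = "character", state = "character"))
  missing_cols <- setdiff(GEO_SCHEMA_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(GEO_SCHEMA_REQUIRED, GEO_SCHEMA_OPTIONAL))
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  for (sd_col in GEO_SCHEMA_OPTIONAL) {
    if (!sd_col %in% names(df)) df[[sd_col]] <- 0
  }
  dup <- df$geo_id[duplicated(df$geo_id)]
  if (length(dup) > 0L) {
    stop("validation error: duplicate geo_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  geos <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    geos[[i]] <- tryCatch(
      geography_inputs(
        geo_id = row$geo_id, state = row$state, area_name = row$area_name,
        metro = as.logical(row$metro),
        chw_wage = wage_dist(row$chw_wage_mean, row$chw_wage_sd),
        supervisor_wages = list(
          RN = wage_dist(row$rn_wage_mean, row$rn_wage_sd),
          MSW = wage_dist(row$msw_wage_mean, row$msw_wage_sd)
        ),
        overhead = overhead_ledger(
          row$oh_equipment, row$oh_software, row$oh_transportation,
          row$oh_space, row$oh_benefits,
          sds = stats::setNames(
            as.numeric(row[GEO_SCHEMA_OPTIONAL]), OVERHEAD_COMPONENTS)
        ),
        travel_time_hours = row$travel_time_hours,
        employment_weight = row$employment_weight
      ),
      error = function(e) {
        stop("validation error in row ", i, " (geo_id '", row$geo_id, "'): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  stats::setNames(geos, df$geo_id)
}

#' Write geography inputs back to the CSV schema
#'
#' Inverse of [load_geography_inputs()]: serializes a list of
#' [geography_inputs] to the documented CSV schema. Currency fields are held
#' at full precision internally and rounded only here, to 4 decimals for
#' rates (sub-cent precision so that read-back reproduces cents exactly).
#' The optional overhead sd columns are emitted only when some sd is nonzero.
#'
#' @param geos List of [geography_inputs].
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_geography_inputs <- function(geos, path) {
  stopifnot(length(geos) > 0L)
  rows <- lapply(geos, function(g) {
    base <- data.frame(
      geo_id = g$geo_id, state = g$state, area_name = g$area_name,
      metro = g$metro,
      chw_wage_mean = g$chw_wage$mean, chw_wage_sd = g$chw_wage$sd,
      rn_wage_mean = g$supervisor_wages$RN$mean,
      rn_wage_sd = g$supervisor_wages$RN$sd,
      msw_wage_mean = g$supervisor_wages$MSW$mean,
      msw_wage_sd = g$supervisor_wages$MSW$sd,
      stringsAsFactors = FALSE
    )
    oh <- as.list(g$overhead$rates)
    names(oh) <- paste0("oh_", OVERHEAD_COMPONENTS)
    ohsd <- as.list(g$overhead$sds)
    names(ohsd) <- GEO_SCHEMA_OPTIONAL
    cbind(base, as.data.frame(oh), travel_time_hours = g$travel_time_hours,
          employment_weight = g$employment_weight, as.data.frame(ohsd))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (all(df[GEO_SCHEMA_OPTIONAL] == 0)) {
    df <- df[, setdiff(names(df), GEO_SCHEMA_OPTIONAL)]
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 4)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' Write threshold estimates to a results CSV
#'
#' One row per geography or aggregate, mirroring the published summary-table
#' layout: label, state, FFS mean and 95% CI bounds, PMPM mean and 95% CI
#' bounds. Currency is rounded to cents at serialization only.
#'
#' @param estimates Non-empty list of [threshold_estimate] objects.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_results <- function(estimates, path) {
  if (length(estimates) == 0L) stop("estimates must be non-empty", call. = FALSE)
  df <- estimates_to_df(estimates)
  money <- c("ffs_rate", "ffs_ci_low", "ffs_ci_high",
             "pmpm_rate", "pmpm_ci_low", "pmpm_ci_high")
  df[money] <- lapply(df[money], function(x) sprintf("%.2f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a results CSV written by [write_results()]
#' @param path Path to the results CSV.
#' @return A data.frame with one row per estimate.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(label = "character", state = "character"))
}

#' Write threshold estimates as JSON with draw summaries
#'
#' JSON variant of [write_results()] retaining the per-draw percentile grid
#' (1, 2.5, 5, 25, 50, 75, 95, 97.5, 99) for each outcome when draws were kept.
#'
#' @param estimates Non-empty list of [threshold_estimate] objects.
#' @param path Output JSON path.
#' @return Invisibly, the list serialized.
#' @export
write_results_json <- function(estimates, path) {
  if (length(estimates) == 0L) stop("estimates must be non-empty", call. = FALSE)
  out <- lapply(estimates, function(e) {
    rec <- list(label = e$label, state = e$state,
                ffs = list(mean = e$ffs_rate, ci = c(e$ffs_ci_low, e$ffs_ci_high)),
                pmpm = list(mean = e$pmpm_rate, ci = c(e$pmpm_ci_low, e$pmpm_ci_high)))
    if (!is.null(e$draws)) {
      grid <- c(1, 2.5, 5, 25, 50, 75, 95, 97.5, 99) / 100
      rec$percentiles <- list(
        prob = grid,
        ffs = unname(stats::quantile(e$draws$ffs, grid, type = 7)),
        pmpm = unname(stats::quantile(e$draws$pmpm, grid, type = 7))
      )
    }
    rec
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
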