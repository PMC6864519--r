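#' Read route measurements from CSV
#'
#' Reads the route CSV dialect `route_id,seq,value[,timestamp,lat,lon]`.
#' Values are concentrations; the canonical internal unit is mg/m3 (the
#' unit the QAQI bands are stated in), so `unit = "ug_m3"` divides by
#' 1000 on read. Rows are ordered by `seq` within each route; `seq` must
#' be unique per route, and values must be nonnegative numbers.
#'
#' @param path Path to a CSV file with columns `route_id`, `seq`, `value`
#'   and optionally `timestamp`, `lat`, `lon`.
#' @param unit Unit of the `value` column: `"mg_m3"` (default) or
#'   `"ug_m3"`.
#' @return A tibble with columns `route_id`, `seq`, `value` (mg/m3) plus
#'   any optional columns present.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("route_id,seq,value", "X1,1,0.036", "X1,2,0.439"), path)
#' read_routes_csv(path)
#' @export
read_routes_csv <- function(path, unit = c("mg_m3", "ug_m3")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("route_id", "seq", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("Routes CSV is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (!is.numeric(data$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(data$value))))[1]
    abort(sprintf("Non-numeric concentration in row %d.", bad))
  }
  bad <- which(is.na(data$value) | data$value < 0 | !is.finite(data$value))
  if (length(bad) > 0) {
    abort(sprintf("Negative or missing concentration in row %d.", bad[1]))
  }
  if (anyDuplicated(data[c("route_id", "seq")])) {
    abort("Duplicate (route_id, seq) pairs are not allowed.")
  }
  data$route_id <- as.character(data$route_id)
  data <- dplyr::arrange(data, match(.data$route_id, unique(.data$route_id)),
                         .data$seq)
  if (unit == "ug_m3") data$value <- data$value / 1000
  keep <- c(required, intersect(c("timestamp", "lat", "lon"), names(data)))
  tibble::as_tibble(data[keep])
}

#' @rdname read_routes_csv
#' @param data A routes data frame (`route_id`, `seq`, `value`, optional
#'   `timestamp`, `lat`, `lon`), values in mg/m3.
#' @export
write_routes_csv <- function(data, path, unit = c("mg_m3", "ug_m3")) {
  unit <- match.arg(unit)
  data <- check_routes_df(data)
  if (!"seq" %in% names(data)) {
    data <- dplyr::mutate(data, seq = dplyr::row_number(), .by = "route_id")
  }
  out <- data[c("route_id", "seq", "value",
                intersect(c("timestamp", "lat", "lon"), names(data)))]
  if (unit == "ug_m3") out$value <- out$value * 1000
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write and re-read a study analysis report
#'
#' `write_report()` saves a full-analysis report ([run_full_analysis()])
#' into a directory: `report.json` holds every table plus the echoed
#' configuration at full precision, and each table is additionally
#' exported as its own CSV (`summary.csv`, `median_ci.csv`,
#' `classification.csv`, `contingency.csv`, `scale.csv`,
#' `group_comparison.csv`). `read_report()` loads the JSON back into the
#' same structure; a write/read round trip preserves all values exactly.
#'
#' @param report A `pm_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `write_report()` returns `dir` invisibly; `read_report()`
#'   returns a `pm_report`.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "pm_report")) abort("`report` must be a `pm_report`.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory: %s", dir))
  tables <- report_tables(report)
  payload <- c(
    lapply(tables, function(tb) as.data.frame(tb)),
    list(config = report$config, errors = report$errors)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

report_tables <- function(report) {
  cls <- report$classification
  cls$candidates <- vapply(cls$candidates, paste, character(1), collapse = "|")
  list(
    summary = report$summary,
    median_ci = report$median_ci,
    classification = cls,
    contingency = report$contingency,
    scale = report$scale,
    group_comparison = if (is.null(report$comparison)) {
      tibble::tibble()
    } else {
      tidy(report$comparison)
    }
  )
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) abort(sprintf("No report.json under %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(x) {
    if (is.null(x) || length(x) == 0) tibble::tibble() else tibble::as_tibble(x)
  }
  cls <- as_tb(raw$classification)
  if (nrow(cls) > 0) {
    cls$candidates <- strsplit(cls$candidates, "|", fixed = TRUE)
  }
  comparison <- if (is.null(raw$group_comparison) ||
                    length(raw$group_comparison) == 0) {
    NULL
  } else {
    row <- raw$group_comparison
    structure(
      list(w = row$statistic, expected = row$expected,
           variance = row$variance, z = row$z, p_value = row$p.value),
      class = "pm_ranksum"
    )
  }
  structure(
    list(
      summary = as_tb(raw$summary),
      median_ci = as_tb(raw$median_ci),
      classification = cls,
      contingency = as_tb(raw$contingency),
      scale = as_tb(raw$scale),
      comparison = comparison,
      config = raw$config,
      errors = raw$errors
    ),
    class = "pm_report"
  )
}
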