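#' Run the full route analysis pipeline
#'
#' Orchestrates the complete analysis on either measured routes (`data`) or
#' a synthetic study (`study` + `seed`): per-route summary statistics,
#' moving-average smoothing, exact median confidence intervals, QAQI band
#' classification, trimmed-mean location sweep, and scale estimates with
#' the biweight and subrange sweep curves; then the group-by-band
#' contingency table and the one-sided rank-sum group comparison. A stage
#' that fails for one route (e.g. a median interval on too few
#' observations) is recorded in `errors` and the pipeline continues with
#' the remaining routes and stages.
#'
#' @param data A routes data frame (`route_id`, `value`, optionally `seq`);
#'   exactly one of `data` and `study` must be given.
#' @param study A [study_spec()] to simulate with [generate_study()].
#' @param seed Integer seed used when generating from `study`.
#' @param groups A data frame (`route_id`, `group`); defaults to the study
#'   spec's groups, or to the first character of each route id.
#' @param alpha Significance level for median intervals (default 0.05).
#' @param window Moving-average window (default 10).
#' @param bands Band system for classification (default [qaqi_bands()]).
#' @param y_group Designated group for the one-sided comparison.
#' @param n_alpha Grid size for the trimmed-mean sweep.
#' @param c_grid,alpha_grid Sweep grids for [route_scale_curves()].
#' @param output_dir If non-NULL, the report is also written there with
#'   [write_report()].
#' @param verbose Log each stage with its parameters via [message()].
#' @return An object of class `pm_report`: a list with tibbles `summary`,
#'   `smoothed`, `median_ci`, `classification`, `contingency`, `scale`,
#'   `trimmed_curves`, `scale_curves`, the `pm_ranksum` `comparison`, the
#'   echoed `config`, and an `errors` tibble (`route_id`, `stage`,
#'   `message`).
#' @examples
#' report <- run_full_analysis(study = six_route_study(), seed = 1)
#' report$contingency
#' @export
run_full_analysis <- function(data = NULL, study = NULL, seed = 1L,
                              groups = NULL, alpha = 0.05, window = 10L,
                              bands = qaqi_bands(), y_group = "Y",
                              n_alpha = 99L,
                              c_grid = seq(0.1, 18, by = 0.1),
                              alpha_grid = seq(0.005, 0.495, by = 0.005),
                              output_dir = NULL, verbose = FALSE) {
  if (is.null(data) == is.null(study)) {
    abort("Provide exactly one of `data` (measurements) or `study` (synthetic spec).")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  log_stage <- function(...) if (verbose) message("[pmroutes] ", sprintf(...))
  if (!is.null(study)) {
    log_stage("simulate: %d routes, seed %d", length(study$routes), seed)
    if (is.null(groups)) groups <- study$groups
    data <- generate_study(study, seed = seed)
  }
  data <- check_routes_df(data)
  ids <- unique(data$route_id)
  if (is.null(groups)) {
    groups <- tibble::tibble(route_id = ids, group = substr(ids, 1, 1))
  }

  errors <- list()
  per_route <- function(stage, f) {
    rows <- lapply(ids, function(id) {
      tryCatch(f(data[data$route_id == id, , drop = FALSE]),
               error = function(e) {
                 errors[[length(errors) + 1]] <<- tibble::tibble(
                   route_id = id, stage = stage,
                   message = conditionMessage(e)
                 )
                 NULL
               })
    })
    dplyr::bind_rows(rows)
  }

  log_stage("summary statistics")
  summary <- per_route("summary", route_summary)
  log_stage("moving average, window %d", window)
  smoothed <- per_route("smooth", function(d) smooth_routes(d, window))
  log_stage("median confidence intervals, alpha %g", alpha)
  ci <- per_route("median_ci", function(d) route_median_ci(d, alpha))
  log_stage("QAQI classification")
  classification <- if (nrow(ci) > 0) {
    classify_routes(ci, bands)
  } else {
    classify_routes(tibble::tibble(route_id = character(), lower = double(),
                                   upper = double()), bands)
  }
  log_stage("trimmed-mean sweep, %d grid points", n_alpha)
  trimmed <- per_route("trimmed_curve",
                       function(d) route_trimmed_curve(d, n_alpha = n_alpha,
                                                       ci_alpha = alpha))
  log_stage("scale estimates and sweeps")
  scale <- per_route("scale_table", route_scale_table)
  curves <- per_route("scale_curves",
                      function(d) route_scale_curves(d, c_grid, alpha_grid))

  contingency <- tryCatch(
    band_contingency(classification, groups, bands),
    error = function(e) {
      errors[[length(errors) + 1]] <<- tibble::tibble(
        route_id = NA_character_, stage = "contingency",
        message = conditionMessage(e))
      tibble::tibble()
    })
  log_stage("group comparison, designated group %s", y_group)
  comparison <- tryCatch(
    compare_band_groups(classification, groups, bands, y_group),
    error = function(e) {
      errors[[length(errors) + 1]] <<- tibble::tibble(
        route_id = NA_character_, stage = "compare_groups",
        message = conditionMessage(e))
      NULL
    })

  report <- structure(
    list(
      summary = summary, smoothed = smoothed, median_ci = ci,
      classification = classification, contingency = contingency,
      scale = scale, trimmed_curves = trimmed, scale_curves = curves,
      comparison = comparison,
      config = list(alpha = alpha, window = as.integer(window),
                    seed = as.integer(seed), n_alpha = as.integer(n_alpha),
                    y_group = y_group,
                    bands = as.data.frame(bands[c("band", "lower", "upper")]),
                    synthetic = !is.null(study)),
      errors = dplyr::bind_rows(errors)
    ),
    class = "pm_report"
  )
  if (!is.null(output_dir)) {
    log_stage("writing report to %s", output_dir)
    write_report(report, output_dir)
  }
  report
}

#' @export
print.pm_report <- function(x, ...) {
  cat("PM2.5 route analysis report\n")
  cat(sprintf("  routes: %d   alpha: %g   MA window: %d\n",
              nrow(x$summary), x$config$alpha, x$config$window))
  if (nrow(x$summary) > 0) {
    cat("  summary:\n")
    print(x$summary)
  }
  if (!is.null(x$comparison)) {
    cat("  group comparison: ")
    print(x$comparison)
  }
  if (!is.null(x$errors) && nrow(x$errors) > 0) {
    cat(sprintf("  %d stage error(s); see $errors\n", nrow(x$errors)))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pm_report <- function(x, ...) {
  tibble::tibble(
    n_routes = nrow(x$summary),
    alpha = x$config$alpha,
    window = x$config$window,
    w = if (is.null(x$comparison)) NA_real_ else x$comparison$w,
    p.value = if (is.null(x$comparison)) NA_real_ else x$comparison$p_value,
    n_errors = if (is.null(x$errors)) 0L else nrow(x$errors)
  )
}
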