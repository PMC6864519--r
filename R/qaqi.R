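#' Quito Air Quality Index bands for PM2.5
#'
#' The QAQI classifies 24-h average PM2.5 concentrations (mg/m3) into six
#' contiguous half-open bands: Desirable [0, 0.025), Acceptable
#' [0.025, 0.050), Caution [0.050, 0.150), Alert [0.150, 0.250), Alarm
#' [0.250, 0.350) and Emergency [0.350, Inf). `band_system()` builds a
#' custom system from band names and breakpoints so other AQI definitions
#' can be swapped in.
#'
#' @return A tibble of class `pm_band_system` with columns `band`, `lower`
#'   (inclusive), `upper` (exclusive) and `ordinal`.
#' @examples
#' qaqi_bands()
#' @export
qaqi_bands <- function() {
  band_system(
    names = c("Desirable", "Acceptable", "Caution", "Alert", "Alarm",
              "Emergency"),
    breaks = c(0, 0.025, 0.050, 0.150, 0.250, 0.350, Inf)
  )
}

#' @rdname qaqi_bands
#' @param names Character vector of band names, from cleanest upward.
#' @param breaks Numeric vector of `length(names) + 1` breakpoints starting
#'   at 0 and ending at `Inf`; band i is `[breaks[i], breaks[i + 1])`.
#' @export
band_system <- function(names, breaks) {
  if (length(breaks) != length(names) + 1) {
    abort("`breaks` must have one more element than `names`.")
  }
  if (breaks[1] != 0 || !is.infinite(breaks[length(breaks)])) {
    abort("Bands must cover [0, Inf): `breaks` must start at 0 and end at Inf.")
  }
  if (any(diff(breaks) <= 0)) abort("`breaks` must be strictly increasing.")
  if (anyDuplicated(names)) abort("Band names must be unique.")
  structure(
    tibble::tibble(
      band = as.character(names),
      lower = breaks[-length(breaks)],
      upper = breaks[-1],
      ordinal = seq_along(names)
    ),
    class = c("pm_band_system", class(tibble::tibble()))
  )
}

#' Classify concentrations into air-quality bands
#'
#' Assigns each nonnegative concentration the unique half-open band that
#' contains it. The mapping is monotone in the band order.
#'
#' @param x Numeric vector of concentrations (mg/m3), all >= 0.
#' @param bands A band system from [qaqi_bands()] or [band_system()].
#' @return Character vector of band names.
#' @examples
#' classify_value(c(0, 0.025, 0.036, 0.40))
#' @export
classify_value <- function(x, bands = qaqi_bands()) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (anyNA(x) || any(x < 0)) abort("Concentrations must be nonnegative and non-missing.")
  bands$band[findInterval(x, bands$lower)]
}

#' Classify route median intervals into bands
#'
#' For each route's median confidence interval, reports both the candidate
#' set (every band the interval intersects — the set of levels the median
#' cannot be ruled out of) and a single conservative label: the band
#' containing the interval's upper endpoint. The label is always a member
#' of the candidate set, which is an interval of consecutive bands.
#'
#' @param ci A data frame with columns `route_id`, `lower`, `upper` (from
#'   [route_median_ci()] or equivalent).
#' @param bands A band system.
#' @return A tibble with columns `route_id`, `lower`, `upper`, `candidates`
#'   (list column of band-name character vectors) and `band` (the
#'   conservative label).
#' @examples
#' ci <- tibble::tibble(route_id = "Y3", lower = 0.038, upper = 0.057)
#' classify_routes(ci)$band # "Caution"
#' @export
classify_routes <- function(ci, bands = qaqi_bands()) {
  if (!is.data.frame(ci)) abort("`ci` must be a data frame.")
  missing <- setdiff(c("route_id", "lower", "upper"), names(ci))
  if (length(missing) > 0) {
    abort(paste0("`ci` is missing column(s): ", paste(missing, collapse = ", "), "."))
  }
  if (nrow(ci) > 0 && any(ci$lower > ci$upper)) abort("Interval `lower` must not exceed `upper`.")
  candidates <- purrr::map2(ci$lower, ci$upper, function(lo, hi) {
    # band [bl, bu) intersects closed [lo, hi] iff bl <= hi and lo < bu
    bands$band[bands$lower <= hi & lo < bands$upper]
  })
  tibble::tibble(
    route_id = ci$route_id,
    lower = ci$lower, upper = ci$upper,
    candidates = candidates,
    band = classify_value(ci$upper, bands)
  )
}

#' Group-by-band contingency table
#'
#' Counts routes per (group, band), restricted to bands that actually
#' occur, with row and column totals.
#'
#' @param labels A data frame with columns `route_id` and `band` (e.g. from
#'   [classify_routes()]).
#' @param groups A data frame with columns `route_id` and `group`.
#' @param bands A band system (fixes the band column order).
#' @return A tibble with a `group` column, one count column per occurring
#'   band, a `Total` column, and a final `Total` row.
#' @export
band_contingency <- function(labels, groups, bands = qaqi_bands()) {
  joined <- join_groups(labels, groups)
  present <- bands$band[bands$band %in% unique(joined$band)]
  counts <- joined |>
    dplyr::count(.data$group, .data$band) |>
    tidyr::pivot_wider(names_from = "band", values_from = "n",
                       values_fill = 0L)
  counts <- counts[, c("group", present), drop = FALSE]
  counts$Total <- rowSums(counts[present])
  totals <- dplyr::summarise(counts, group = "Total",
                             dplyr::across(dplyr::where(is.numeric), sum))
  dplyr::bind_rows(counts, totals)
}

#' Compare two route groups on the band ordinal scale
#'
#' Encodes each route by the ordinal index of its band and runs the
#' one-sided tie-corrected Wilcoxon rank-sum test ([ranksum_test()]) with
#' the designated group as the sample hypothesized to be stochastically
#' larger (H1: pollution in `y_group` exceeds the other group).
#'
#' @inheritParams band_contingency
#' @param y_group Group label of the designated (alternative "greater")
#'   sample; default "Y".
#' @return A `pm_ranksum` object.
#' @examples
#' labels <- tibble::tibble(
#'   route_id = c("X1", "X2", "X3", "Y1", "Y2", "Y3"),
#'   band = c("Acceptable", "Acceptable", "Desirable",
#'            "Desirable", "Acceptable", "Caution")
#' )
#' groups <- tibble::tibble(route_id = labels$route_id,
#'                          group = substr(labels$route_id, 1, 1))
#' compare_band_groups(labels, groups)$w # 11.5
#' @export
compare_band_groups <- function(labels, groups, bands = qaqi_bands(),
                                y_group = "Y") {
  joined <- join_groups(labels, groups)
  if (!y_group %in% joined$group) {
    abort(sprintf("Group \"%s\" has no routes.", y_group))
  }
  if (length(unique(joined$group)) != 2) {
    abort("Exactly two groups are required for the comparison.")
  }
  ord <- setNames(bands$ordinal, bands$band)
  unknown <- setdiff(joined$band, bands$band)
  if (length(unknown) > 0) {
    abort(paste0("Unknown band label(s): ", paste(unknown, collapse = ", "), "."))
  }
  scores <- ord[joined$band]
  ranksum_test(y = scores[joined$group == y_group],
               x = scores[joined$group != y_group])
}

join_groups <- function(labels, groups) {
  for (nm in c("route_id", "band")) {
    if (!nm %in% names(labels)) abort(sprintf("`labels` needs a `%s` column.", nm))
  }
  for (nm in c("route_id", "group")) {
    if (!nm %in% names(groups)) abort(sprintf("`groups` needs a `%s` column.", nm))
  }
  joined <- dplyr::inner_join(
    dplyr::select(labels, "route_id", "band"),
    dplyr::select(groups, "route_id", "group"),
    by = "route_id"
  )
  if (nrow(joined) < nrow(labels)) {
    missing <- setdiff(labels$route_id, groups$route_id)
    abort(paste0("Route(s) without a group assignment: ",
                 paste(missing, collapse = ", "), "."))
  }
  joined
}
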