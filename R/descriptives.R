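#' Summary statistics for concentration series
#'
#' Computes the per-route descriptive summary used throughout the analysis:
#' count, mean, median, standard deviation (divisor n - 1), skewness,
#' kurtosis, minimum and maximum. Skewness is \eqn{m_3 / m_2^{3/2}} and
#' kurtosis the non-excess \eqn{m_4 / m_2^2} (a normal sample approaches 3),
#' with \eqn{m_k} the k-th central moment using divisor n. Shape statistics
#' need at least two observations and nonzero variance; otherwise they are
#' reported as `NA`.
#'
#' @param data A data frame with columns `route_id` and `value`
#'   (concentrations in mg/m3).
#' @return A tibble with one row per route and columns `route_id`, `count`,
#'   `mean`, `median`, `sd`, `skewness`, `kurtosis`, `minimum`, `maximum`.
#' @examples
#' routes <- tibble::tibble(route_id = "X1", value = c(0, 1, 2, 3, 4))
#' route_summary(routes)
#' @export
route_summary <- function(data) {
  by_route(data, function(x) {
    x <- check_values(x)
    tibble::as_tibble(summary_stats(x))
  })
}

#' @rdname route_summary
#' @param values Numeric vector of concentrations.
#' @return For `summary_stats()`, a named list with the same fields.
#' @export
summary_stats <- function(values) {
  x <- check_values(values)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (n >= 2 && m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  list(
    count = n,
    mean = m,
    median = median(x),
    sd = if (n >= 2) sd(x) else NA_real_,
    skewness = skew,
    kurtosis = kurt,
    minimum = min(x),
    maximum = max(x)
  )
}

#' Tukey hinge quartiles
#'
#' Quartiles by the Tukey hinge rule: the median splits the sorted sample
#' into halves, each half including the median element when n is odd, and
#' the hinges are the medians of the halves. Used consistently for the
#' trimean, the semi-interquartile range, and box-plot fences.
#'
#' @param values Numeric vector (any order).
#' @return A named list with `q1`, `q2`, `q3`.
#' @examples
#' tukey_hinges(c(1, 2, 3, 4, 5)) # q1 = 2, q2 = 3, q3 = 4
#' @export
tukey_hinges <- function(values) {
  x <- sort(check_values(values))
  n <- length(x)
  half <- ceiling(n / 2)
  list(
    q1 = median(x[seq_len(half)]),
    q2 = median(x),
    q3 = median(x[seq.int(n - half + 1L, n)])
  )
}

#' Centered moving-average smoothing
#'
#' Smooths each route with a centered moving average of nominal size
#' `window`. Output length equals input length: near the series ends the
#' window is truncated to the in-range observations, so the ends are
#' maintained rather than dropped.
#'
#' @param data A data frame with columns `route_id` and `value`, rows in
#'   time order within each route.
#' @param window Positive integer window size (default 10, the size used for
#'   the route trend plots).
#' @return `data` with `value` replaced by the smoothed series.
#' @examples
#' routes <- tibble::tibble(route_id = "X1", value = c(1, 2, 3, 4, 5))
#' smooth_routes(routes, window = 3)$value # 1.5 2 3 4 4.5
#' @export
smooth_routes <- function(data, window = 10L) {
  data <- check_routes_df(data)
  out <- data
  for (id in unique(data$route_id)) {
    sel <- data$route_id == id
    out$value[sel] <- moving_average(data$value[sel], window)
  }
  out
}

#' @rdname smooth_routes
#' @param values Numeric vector in time order.
#' @export
moving_average <- function(values, window = 10L) {
  x <- check_values(values)
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != floor(window)) {
    abort("`window` must be a positive integer.")
  }
  window <- as.integer(window)
  n <- length(x)
  lo <- (window - 1L) %/% 2L      # observations taken before the centre
  hi <- window %/% 2L             # and after, for even windows one more after
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Box-plot statistics with Tukey fences
#'
#' Hinge-based box-plot components: whiskers extend to the most extreme
#' observations within 1.5 interquartile ranges of the hinges, and points
#' beyond the fences are flagged as outliers.
#'
#' @inheritParams tukey_hinges
#' @return A list with `q1`, `q2`, `q3`, `whisker_low`, `whisker_high`, and
#'   the numeric vector `outliers`.
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))$outliers # 100
#' @export
boxplot_stats <- function(values) {
  x <- check_values(values)
  q <- tukey_hinges(x)
  iqr <- q$q3 - q$q1
  lo_fence <- q$q1 - 1.5 * iqr
  hi_fence <- q$q3 + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(
    q1 = q$q1, q2 = q$q2, q3 = q$q3,
    whisker_low = min(x[inside]),
    whisker_high = max(x[inside]),
    outliers = sort(x[!inside])
  )
}

#' Notch-style empirical confidence interval for the median
#'
#' The McGill notch interval, median +/- 1.57 * IQR / sqrt(n), with the IQR
#' from Tukey hinges. A quick large-sample interval; the exact
#' order-statistic interval is [route_median_ci()].
#'
#' @inheritParams tukey_hinges
#' @param level Nominal confidence level (fixed shape; retained for the
#'   record, the 1.57 constant corresponds to 95%).
#' @return A named list with `median`, `lower`, `upper`.
#' @examples
#' empirical_median_ci(c(1, 2, 3, 4)) # 2.5 +/- 1.57
#' @export
empirical_median_ci <- function(values, level = 0.95) {
  x <- check_values(values)
  q <- tukey_hinges(x)
  half <- 1.57 * (q$q3 - q$q1) / sqrt(length(x))
  list(median = q$q2, lower = q$q2 - half, upper = q$q2 + half)
}

#' @rdname empirical_median_ci
#' @inheritParams route_summary
#' @return For `route_empirical_ci()`, a tibble with one row per route.
#' @export
route_empirical_ci <- function(data, level = 0.95) {
  by_route(data, function(x) tibble::as_tibble(empirical_median_ci(x, level)))
}
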