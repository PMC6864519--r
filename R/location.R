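#' Alpha-trimmed mean
#'
#' Mean of the order statistics after discarding the `floor(n * alpha)`
#' smallest and largest observations:
#' \deqn{\bar\Psi(\alpha) = \frac{1}{n - 2\lfloor n\alpha\rfloor}
#'   \sum_{i=\lfloor n\alpha\rfloor + 1}^{n - \lfloor n\alpha\rfloor} \Psi_{(i)}.}
#' At alpha = 0 this is the arithmetic mean; as alpha approaches 0.5 it
#' approaches the median.
#'
#' @param values Numeric vector of concentrations (mg/m3).
#' @param alpha Trimming fraction in [0, 0.5).
#' @return The trimmed mean (mg/m3).
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 100), 0.2) # 3
#' @export
trimmed_mean <- function(values, alpha) {
  x <- sort(check_values(values))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 0.5) {
    abort("`alpha` must be a single value in [0, 0.5).")
  }
  n <- length(x)
  g <- floor(n * alpha + 1e-9) # guard against 0.1 * 5 = 0.4999... artifacts
  mean(x[seq.int(g + 1L, n - g)])
}

#' Trimean
#'
#' The hinge-weighted location estimate (Q1 + 2 Q2 + Q3) / 4, with the
#' quartiles taken as Tukey hinges ([tukey_hinges()]).
#'
#' @inheritParams trimmed_mean
#' @return The trimean (mg/m3).
#' @examples
#' trimean(c(1, 2, 3, 4, 5)) # 3
#' @export
trimean <- function(values) {
  q <- tukey_hinges(values)
  (q$q1 + 2 * q$q2 + q$q3) / 4
}

#' Trimmed-mean sweep across the trimming fraction
#'
#' Evaluates the alpha-trimmed mean over an even grid of trimming fractions
#' for each route, and attaches the route's mean, median, trimean and exact
#' median confidence interval for comparison. The curve is a staircase:
#' estimates change only when `floor(n * alpha)` increments.
#'
#' @param data A data frame with columns `route_id` and `value`.
#' @param n_alpha Number of grid points, evenly spaced from 0 to `max_alpha`
#'   (default 99 points to 0.49).
#' @param max_alpha Largest trimming fraction on the grid (< 0.5).
#' @param ci_alpha Significance level for the attached median interval;
#'   routes too small for the interval get `NA` bands.
#' @return A tibble of class `pm_trimmed_curve` with columns `route_id`,
#'   `alpha`, `estimate`, and a `reference` attribute holding the per-route
#'   mean, median, trimean, and CI band. Supports [autoplot()].
#' @examples
#' routes <- tibble::tibble(route_id = "X1", value = c(1, 2, 3, 4, 100))
#' curve <- route_trimmed_curve(routes, n_alpha = 5)
#' @export
route_trimmed_curve <- function(data, n_alpha = 99L, max_alpha = 0.49,
                                ci_alpha = 0.05) {
  data <- check_routes_df(data)
  if (max_alpha >= 0.5 || max_alpha < 0) abort("`max_alpha` must be in [0, 0.5).")
  grid <- seq(0, max_alpha, length.out = n_alpha)
  curve <- by_route(data, function(x) {
    tibble::tibble(
      alpha = grid,
      estimate = vapply(grid, function(a) trimmed_mean(x, a), numeric(1))
    )
  })
  reference <- by_route(data, function(x) {
    band <- tryCatch(median_ci(x, ci_alpha),
                     error = function(e) list(lower = NA_real_, upper = NA_real_))
    tibble::tibble(
      mean = mean(x), median = median(x), trimean = trimean(x),
      ci_lower = band$lower, ci_upper = band$upper
    )
  })
  structure(curve, reference = reference,
            class = c("pm_trimmed_curve", class(curve)))
}
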