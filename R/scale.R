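#' Classical and robust scale estimators
#'
#' The seven dispersion estimates used for route concentration series. All
#' satisfy shift invariance, S(x + lambda) = S(x), and absolute scale
#' equivariance, S(lambda x) = |lambda| S(x).
#'
#' * `mean_abs_dev()` — mean absolute deviation about the mean.
#' * `sample_sd()` — sample standard deviation, divisor n - 1.
#' * `mad_raw()` — median absolute deviation about the median, UNSCALED (no
#'   1.4826 normal-consistency factor; for normal data its expectation is
#'   close to (2/3) sigma).
#' * `sir()` — semi-interquartile range (Q3 - Q1)/2 with Tukey hinges.
#' * `sbi_scale()` — square root of the biweight midvariance
#'   [biweight_midvariance()].
#' * `subrange_scale()` — normalized shortest subrange estimator.
#' * `lms_scale()` — least-median-of-squares scale: half the shortest
#'   window spanning `floor(n/2)` order-statistic gaps.
#'
#' @param values Numeric vector of concentrations (mg/m3).
#' @return A nonnegative scale estimate (mg/m3).
#' @examples
#' mean_abs_dev(c(1, 2, 3, 4, 100)) # 31.2
#' mad_raw(c(1, 2, 3, 4, 100))      # 1
#' lms_scale(c(1, 2, 3, 4, 100))    # 1
#' @name scale_estimators
NULL

#' @rdname scale_estimators
#' @export
mean_abs_dev <- function(values) {
  x <- check_values(values)
  mean(abs(x - mean(x)))
}

#' @rdname scale_estimators
#' @export
sample_sd <- function(values) {
  x <- check_values(values, min_n = 2L)
  sd(x)
}

#' @rdname scale_estimators
#' @export
mad_raw <- function(values) {
  x <- check_values(values)
  median(abs(x - median(x)))
}

#' @rdname scale_estimators
#' @export
sir <- function(values) {
  q <- tukey_hinges(values)
  (q$q3 - q$q1) / 2
}

#' Biweight midvariance
#'
#' M-estimator-based scale measure. With M the sample median and D the raw
#' MAD, deviations are standardized as u_i = (x_i - M) / (c D); only
#' observations with |u_i| < 1 contribute:
#' \deqn{S^2_{bi}(c) = \frac{n \sum_A (x_i - M)^2 (1 - u_i^2)^4}
#'   {\big(\sum_A (1 - u_i^2)(1 - 5 u_i^2)\big)^2}.}
#' Because MAD has expectation close to (2/3) sigma for normal data, the
#' tuning constant c = 9 discards observations more than roughly six
#' standard deviations from the centre. As c grows the midvariance tends to
#' the plain average squared deviation about the median. When D = 0 the
#' sample has zero robust dispersion and 0 is returned.
#'
#' @inheritParams scale_estimators
#' @param c Positive tuning constant.
#' @return `biweight_midvariance()` returns the midvariance (squared
#'   scale); `sbi_scale()` its square root, on the mg/m3 scale.
#' @examples
#' biweight_midvariance(c(0, 1, 2, 3, 4), c = 9) # ~2.297
#' @export
biweight_midvariance <- function(values, c = 9) {
  x <- check_values(values)
  if (!is.numeric(c) || length(c) != 1 || c <= 0) {
    abort("`c` must be a single positive number.")
  }
  m <- median(x)
  d <- mad_raw(x)
  if (d == 0) return(0)
  u <- (x - m) / (c * d)
  keep <- abs(u) < 1
  num <- length(x) * sum(((x - m)^2 * (1 - u^2)^4)[keep])
  den <- sum(((1 - u^2) * (1 - 5 * u^2))[keep])^2
  num / den
}

#' @rdname biweight_midvariance
#' @export
sbi_scale <- function(values, c = 9) {
  sqrt(biweight_midvariance(values, c))
}

#' @rdname scale_estimators
#' @param alpha Subrange fraction in (0, 0.5). With h = floor(alpha * n) + 1,
#'   the raw estimate is the minimum of X(i + h) - X(i) over all valid start
#'   indices, normalized by qnorm(0.75) - qnorm(0.75 - alpha) for
#'   normal consistency.
#' @export
subrange_scale <- function(values, alpha) {
  x <- sort(check_values(values))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 0.5) {
    abort("`alpha` must be a single value in (0, 0.5).")
  }
  n <- length(x)
  h <- floor(alpha * n + 1e-9) + 1L
  if (n < h + 1L) {
    abort(sprintf("Need at least %d observations for alpha = %g.", h + 1L, alpha))
  }
  raw <- min(x[seq.int(1L + h, n)] - x[seq_len(n - h)])
  raw / (qnorm(0.75) - qnorm(0.75 - alpha))
}

#' @rdname scale_estimators
#' @export
lms_scale <- function(values) {
  x <- sort(check_values(values, min_n = 2L))
  n <- length(x)
  half <- n %/% 2L
  0.5 * min(x[seq.int(1L + half, n)] - x[seq_len(n - half)])
}

#' Per-route scale-estimate table and sweep curves
#'
#' `route_scale_table()` computes the five point estimates (MAD about the
#' mean, sample SD, raw MAD, SIR, LMS) for each route.
#' `route_scale_curves()` sweeps the biweight scale S_bi(c) over the tuning
#' constant and the subrange estimator C_n(alpha) over the subrange
#' fraction, mirroring the ranges 0 < c < 18 and 0 < alpha < 0.5.
#'
#' @param data A data frame with columns `route_id` and `value`.
#' @return `route_scale_table()`: a tibble with columns `route_id`,
#'   `mad_mean`, `sd`, `mad`, `sir`, `lms`. `route_scale_curves()`: a tibble
#'   of class `pm_scale_curves` with columns `route_id`, `family` ("sbi" or
#'   "cn"), `parameter` (c or alpha) and `estimate`; supports [autoplot()].
#' @examples
#' routes <- tibble::tibble(route_id = "X1", value = c(1, 2, 3, 4, 100))
#' route_scale_table(routes)
#' @export
route_scale_table <- function(data) {
  by_route(data, function(x) {
    tibble::tibble(
      mad_mean = mean_abs_dev(x),
      sd = if (length(x) >= 2) sample_sd(x) else NA_real_,
      mad = mad_raw(x),
      sir = sir(x),
      lms = if (length(x) >= 2) lms_scale(x) else NA_real_
    )
  })
}

#' @rdname route_scale_table
#' @param c_grid Grid of biweight tuning constants (default 0.1 to 18 in
#'   steps of 0.1).
#' @param alpha_grid Grid of subrange fractions (default 0.005 to 0.495 in
#'   steps of 0.005); values too large for a route's n are skipped.
#' @export
route_scale_curves <- function(data,
                               c_grid = seq(0.1, 18, by = 0.1),
                               alpha_grid = seq(0.005, 0.495, by = 0.005)) {
  out <- by_route(data, function(x) {
    sbi <- tibble::tibble(
      family = "sbi", parameter = c_grid,
      estimate = vapply(c_grid, function(cc) sbi_scale(x, cc), numeric(1))
    )
    ok <- floor(alpha_grid * length(x) + 1e-9) + 1L <= length(x) - 1L
    cn <- tibble::tibble(
      family = "cn", parameter = alpha_grid[ok],
      estimate = vapply(alpha_grid[ok], function(a) subrange_scale(x, a),
                        numeric(1))
    )
    dplyr::bind_rows(sbi, cn)
  })
  structure(out, class = c("pm_scale_curves", class(out)))
}
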