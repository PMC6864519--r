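#' Sign test for a hypothesized median
#'
#' Exact binomial sign test of H0: median = m0 against the two-sided
#' alternative. Observations equal to m0 are discarded; with h remaining
#' observations the count K of values above m0 is Binomial(h, 1/2) under
#' H0, and the p-value is min(1, 2 * min(P(K <= k), P(K >= k))).
#'
#' @param values Numeric vector of concentrations (mg/m3).
#' @param m0 Hypothesized median (mg/m3).
#' @return An object of class `pm_sign_test`: a list with `m0`, `k`
#'   (observations above `m0`), `h` (non-tied sample size) and `p_value`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' sign_test(c(1, 2, 3, 4, 5, 6), m0 = 0)$p_value # 2/64
#' @export
sign_test <- function(values, m0) {
  x <- check_values(values)
  if (!is.numeric(m0) || length(m0) != 1 || !is.finite(m0)) {
    abort("`m0` must be a single finite number.")
  }
  keep <- x != m0
  h <- sum(keep)
  if (h == 0) abort("All observations equal `m0`; the sign test is degenerate.")
  k <- sum(x > m0)
  p <- min(1, 2 * min(pbinom(k, h, 0.5), 1 - pbinom(k - 1, h, 0.5)))
  structure(list(m0 = m0, k = k, h = h, p_value = p), class = "pm_sign_test")
}

#' Exact order-statistic confidence interval for the median
#'
#' Equal-tail nonparametric interval built from binomial order-statistic
#' tail probabilities. With K ~ Binomial(n, 1/2), k' is the largest integer
#' with P(K <= k') <= alpha/2 and k the smallest integer with
#' P(K >= k) <= alpha/2; the interval is [X(k'+1), X(k)] in 1-based order
#' statistics, with achieved coverage 1 - P(K <= k') - P(K >= k), always at
#' least 1 - alpha.
#'
#' @inheritParams sign_test
#' @param alpha Significance level (default 0.05).
#' @return An object of class `pm_median_ci`: a list with `alpha`, `n`,
#'   `lower_index`, `upper_index` (1-based order-statistic indices),
#'   `lower`, `upper` (mg/m3) and `coverage`. Supports [tidy()].
#' @examples
#' ci <- median_ci(1:10)
#' c(ci$lower_index, ci$upper_index) # 2, 9
#' @export
median_ci <- function(values, alpha = 0.05) {
  x <- sort(check_values(values))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  n <- length(x)
  half <- alpha / 2
  # largest k' with P(K <= k') <= alpha/2; -1 means no valid k'
  tails_lo <- pbinom(0:n, n, 0.5)
  kp <- max(which(tails_lo <= half), 0L) - 1L
  if (kp < 0) {
    abort(sprintf(
      "Sample too small for level: n = %d cannot support a two-sided interval at alpha = %g.",
      n, alpha
    ))
  }
  # smallest k with P(K >= k) <= alpha/2; symmetric tail => k = n - kp
  k <- n - kp
  cov <- 1 - pbinom(kp, n, 0.5) - (1 - pbinom(k - 1, n, 0.5))
  structure(
    list(
      alpha = alpha, n = n,
      lower_index = kp + 1L, upper_index = k,
      lower = x[kp + 1L], upper = x[k],
      coverage = cov
    ),
    class = "pm_median_ci"
  )
}

#' @rdname median_ci
#' @param data A data frame with columns `route_id` and `value`.
#' @return For `route_median_ci()`, a tibble with one row per route and
#'   columns `route_id`, `n`, `lower_index`, `upper_index`, `lower`,
#'   `upper`, `length` (upper - lower) and `coverage`.
#' @export
route_median_ci <- function(data, alpha = 0.05) {
  by_route(data, function(x) {
    ci <- median_ci(x, alpha)
    tibble::tibble(
      n = ci$n,
      lower_index = ci$lower_index, upper_index = ci$upper_index,
      lower = ci$lower, upper = ci$upper,
      length = ci$upper - ci$lower,
      coverage = ci$coverage
    )
  })
}

#' One-sided tie-corrected Wilcoxon rank-sum test
#'
#' Compares two samples with the rank-sum statistic of the designated
#' sample `y`, using midranks for ties, the tie-corrected variance
#' \deqn{var(W) = \frac{n_x n_y}{12}\Big[(N+1) -
#'   \sum_j \frac{t_j^3 - t_j}{N(N-1)}\Big],}
#' and the normal approximation with continuity correction 0.5. The
#' alternative is one-sided: `y` stochastically larger than `x`.
#'
#' @param y Numeric vector, the designated sample (e.g. group Y band
#'   ordinals).
#' @param x Numeric vector, the reference sample.
#' @return An object of class `pm_ranksum`: a list with `w` (rank-sum of
#'   `y`), `expected`, `variance`, `z` and `p_value` (upper tail). Supports
#'   [tidy()] and [glance()].
#' @examples
#' ranksum_test(y = c(3, 4), x = c(1, 2))$w # 7
#' @export
ranksum_test <- function(y, x) {
  y <- check_values(y, "y")
  x <- check_values(x, "x")
  pooled <- c(y, x)
  n_y <- length(y)
  n_x <- length(x)
  n <- n_y + n_x
  r <- rank(pooled) # midranks for ties
  w <- sum(r[seq_len(n_y)])
  expected <- n_y * (n + 1) / 2
  ties <- table(pooled)
  correction <- sum(ties^3 - ties) / (n * (n - 1))
  variance <- (n_x * n_y / 12) * ((n + 1) - correction)
  if (variance <= 0) {
    abort("All pooled observations are identical; the rank-sum test is degenerate.")
  }
  z <- (w - expected - 0.5) / sqrt(variance)
  structure(
    list(
      w = w, expected = expected, variance = variance,
      z = z, p_value = pnorm(z, lower.tail = FALSE)
    ),
    class = "pm_ranksum"
  )
}

# Tidiers and printing ------------------------------------------------------

#' @exportS3Method generics::tidy
tidy.pm_sign_test <- function(x, ...) {
  tibble::tibble(m0 = x$m0, k = x$k, h = x$h, p.value = x$p_value)
}

#' @exportS3Method generics::glance
glance.pm_sign_test <- function(x, ...) tidy.pm_sign_test(x, ...)

#' @export
print.pm_sign_test <- function(x, ...) {
  cat("Sign test  H0: median =", format(x$m0), "\n")
  cat(sprintf("  k = %d of h = %d above m0, two-sided p = %.4f\n",
              x$k, x$h, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pm_median_ci <- function(x, ...) {
  tibble::tibble(
    n = x$n, alpha = x$alpha,
    lower_index = x$lower_index, upper_index = x$upper_index,
    lower = x$lower, upper = x$upper, coverage = x$coverage
  )
}

#' @export
print.pm_median_ci <- function(x, ...) {
  cat(sprintf(
    "Order-statistic median CI (alpha = %g): [X(%d), X(%d)] = [%g, %g], coverage %.5f\n",
    x$alpha, x$lower_index, x$upper_index, x$lower, x$upper, x$coverage
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pm_ranksum <- function(x, ...) {
  tibble::tibble(
    statistic = x$w, expected = x$expected, variance = x$variance,
    z = x$z, p.value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.pm_ranksum <- function(x, ...) tidy.pm_ranksum(x, ...)

#' @export
print.pm_ranksum <- function(x, ...) {
  cat("One-sided Wilcoxon rank-sum (ties: midranks, continuity correction)\n")
  cat(sprintf("  W = %g, E(W) = %g, var(W) = %g, z = %.4f, p = %.4f\n",
              x$w, x$expected, x$variance, x$z, x$p_value))
  invisible(x)
}
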