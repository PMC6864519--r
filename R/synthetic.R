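#' Specify a synthetic monitoring route
#'
#' Describes one route's generative model: a nonnegative right-skewed body
#' (lognormal, parameterized so its median is `target_median` and the
#' standard deviation of the log-values is `body_scale`), optional additive
#' piecewise trend segments (clipped at zero, emulating the gradual trend
#' changes seen along real routes), and multiplicative spike contamination
#' (a Bernoulli subset of observations multiplied by
#' `contamination_scale`, emulating traffic bursts).
#'
#' @param route_id Route identifier (e.g. "X1").
#' @param n Number of observations (one per 10-s averaging interval).
#' @param target_median Median concentration of the uncontaminated body
#'   (mg/m3, >= 0; 0 gives an all-zero body).
#' @param body_scale Standard deviation of log-concentration
#'   (dimensionless multiplicative spread; 0 gives a constant body).
#' @param contamination_rate Fraction of observations hit by spikes, in
#'   [0, 0.2].
#' @param contamination_scale Multiplier (>= 1) applied to spiked
#'   observations.
#' @param trend_segments List of `c(start_fraction, end_fraction, offset)`
#'   triples; the offset (mg/m3) is added over that fraction of the route
#'   and the result clipped at 0 (a negative offset yields low-side zeros).
#' @param seed Integer seed; the same spec generates bit-identical series.
#' @return An object of class `route_spec`.
#' @examples
#' spec <- route_spec("X1", n = 100, target_median = 0.036, seed = 7)
#' head(generate_route(spec))
#' @export
route_spec <- function(route_id, n, target_median,
                       body_scale = 0.5,
                       contamination_rate = 0,
                       contamination_scale = 1,
                       trend_segments = list(),
                       seed = 1L) {
  if (!is.character(route_id) || length(route_id) != 1 || !nzchar(route_id)) {
    abort("`route_id` must be a non-empty string.")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer.")
  }
  if (!is.numeric(target_median) || length(target_median) != 1 ||
      target_median < 0) {
    abort("`target_median` must be a single nonnegative concentration.")
  }
  if (!is.numeric(body_scale) || length(body_scale) != 1 || body_scale < 0) {
    abort("`body_scale` must be a single nonnegative number.")
  }
  if (!is.numeric(contamination_rate) || length(contamination_rate) != 1 ||
      contamination_rate < 0 || contamination_rate > 0.2) {
    abort("`contamination_rate` must be in [0, 0.2].")
  }
  if (!is.numeric(contamination_scale) || length(contamination_scale) != 1 ||
      contamination_scale < 1) {
    abort("`contamination_scale` must be >= 1.")
  }
  if (!is.list(trend_segments) ||
      !all(vapply(trend_segments, function(s) {
        is.numeric(s) && length(s) == 3 && s[1] >= 0 && s[2] <= 1 && s[1] <= s[2]
      }, logical(1)))) {
    abort("`trend_segments` must be a list of c(start_fraction, end_fraction, offset) with 0 <= start <= end <= 1.")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed)) {
    abort("`seed` must be a single integer.")
  }
  structure(
    list(
      route_id = route_id, n = as.integer(n),
      target_median = target_median, body_scale = body_scale,
      contamination_rate = contamination_rate,
      contamination_scale = contamination_scale,
      trend_segments = trend_segments, seed = as.integer(seed)
    ),
    class = "route_spec"
  )
}

#' Generate one synthetic route series
#'
#' Draws the route described by a [route_spec()]: lognormal body, additive
#' trend segments clipped at zero, then multiplicative spikes on a
#' Bernoulli subset. Deterministic in the spec's seed; all values are
#' nonnegative.
#'
#' @param spec A [route_spec()].
#' @return A tibble with columns `route_id`, `seq` (1-based order) and
#'   `value` (mg/m3).
#' @export
generate_route <- function(spec) {
  if (!inherits(spec, "route_spec")) abort("`spec` must be a `route_spec`.")
  n <- spec$n
  value <- withr_seed(spec$seed, {
    body <- if (spec$target_median > 0) {
      rlnorm(n, meanlog = log(spec$target_median), sdlog = spec$body_scale)
    } else {
      rep(0, n)
    }
    frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    for (seg in spec$trend_segments) {
      hit <- frac >= seg[1] & frac <= seg[2]
      body[hit] <- body[hit] + seg[3]
    }
    body <- pmax(body, 0)
    spikes <- runif(n) < spec$contamination_rate
    body[spikes] <- body[spikes] * spec$contamination_scale
    body
  })
  tibble::tibble(route_id = spec$route_id, seq = seq_len(n), value = value)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Specify and generate a multi-route study
#'
#' A study is a set of routes with a group assignment (e.g. routes parallel
#' to a park, group "X", versus perpendicular, group "Y"). Per-route seeds
#' are derived deterministically from the study seed and the route id, so
#' routes are independent streams and the whole study is reproducible.
#'
#' @param routes List of [route_spec()] objects with unique ids.
#' @param groups A data frame with columns `route_id`, `group` covering
#'   every route; by default each route is assigned the first character of
#'   its id.
#' @return `study_spec()`: an object of class `study_spec`.
#' @examples
#' study <- six_route_study()
#' data <- generate_study(study, seed = 1)
#' dplyr::count(data, route_id)
#' @export
study_spec <- function(routes, groups = NULL) {
  if (!is.list(routes) ||
      !all(vapply(routes, inherits, logical(1), "route_spec"))) {
    abort("`routes` must be a list of `route_spec` objects.")
  }
  ids <- vapply(routes, function(r) r$route_id, character(1))
  if (anyDuplicated(ids)) abort("Route ids must be unique.")
  if (is.null(groups)) {
    groups <- tibble::tibble(route_id = ids, group = substr(ids, 1, 1))
  }
  if (!is.data.frame(groups) ||
      !all(c("route_id", "group") %in% names(groups))) {
    abort("`groups` must be a data frame with columns `route_id` and `group`.")
  }
  if (!setequal(groups$route_id, ids) || anyDuplicated(groups$route_id)) {
    abort("`groups` must assign every route id exactly one group.")
  }
  structure(list(routes = routes, groups = tibble::as_tibble(groups)),
            class = "study_spec")
}

#' @rdname study_spec
#' @param spec A `study_spec`.
#' @param seed Study-level integer seed; per-route seeds are a hash of this
#'   seed and the route id.
#' @return `generate_study()`: a long tibble with columns `route_id`,
#'   `seq`, `value`, one block per route.
#' @export
generate_study <- function(spec, seed = 1L) {
  if (!inherits(spec, "study_spec")) abort("`spec` must be a `study_spec`.")
  series <- lapply(spec$routes, function(r) {
    r$seed <- derive_seed(seed, r$route_id)
    generate_route(r)
  })
  if (length(series) == 0) {
    return(tibble::tibble(route_id = character(), seq = integer(),
                          value = double()))
  }
  dplyr::bind_rows(series)
}

# Deterministic 31-bit hash of (study seed, route id).
derive_seed <- function(seed, route_id) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(route_id)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Six-route study preset
#'
#' A bundled study specification shaped like a six-route mobile campaign
#' around an urban park: route sizes 156, 83, 102, 70, 70, 82; per-route
#' target medians spanning the Desirable, Acceptable and Caution QAQI
#' bands; heavy right-skewed bodies; sparse multiplicative spikes on the
#' busiest routes; and trend segments giving the piecewise drift of real
#' walks (including a clipped negative segment that produces low-side
#' zeros on the largest route).
#'
#' @return A `study_spec` with routes X1, X2, X3 (group "X") and Y1, Y2,
#'   Y3 (group "Y").
#' @export
six_route_study <- function() {
  study_spec(list(
    route_spec("X1", n = 156, target_median = 0.036, body_scale = 0.65,
               contamination_rate = 0.05, contamination_scale = 10,
               trend_segments = list(c(0.00, 0.06, -0.034))),
    route_spec("X2", n = 83, target_median = 0.037, body_scale = 0.12,
               contamination_rate = 0.02, contamination_scale = 1.6),
    route_spec("X3", n = 102, target_median = 0.0095, body_scale = 0.55,
               contamination_rate = 0.02, contamination_scale = 3,
               trend_segments = list(c(0.85, 1.00, -0.006))),
    route_spec("Y1", n = 70, target_median = 0.0085, body_scale = 0.9,
               contamination_rate = 0.03, contamination_scale = 5),
    route_spec("Y2", n = 70, target_median = 0.033, body_scale = 0.45,
               contamination_rate = 0.03, contamination_scale = 4),
    route_spec("Y3", n = 82, target_median = 0.045, body_scale = 0.55,
               contamination_rate = 0.04, contamination_scale = 4,
               trend_segments = list(c(0.40, 0.60, 0.03)))
  ))
}
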