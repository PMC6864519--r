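#' Plot route concentration series
#'
#' Line plot of each route's concentrations in time order, optionally with
#' a moving-average overlay and the QAQI band boundaries.
#'
#' @param data A routes data frame (`route_id`, `value`, optional `seq`).
#' @param window If non-NULL, overlay the centered moving average of this
#'   size.
#' @param bands If non-NULL, draw horizontal band boundaries.
#' @return A ggplot object, faceted by route.
#' @export
plot_routes <- function(data, window = NULL, bands = NULL) {
  data <- check_routes_df(data)
  if (!"seq" %in% names(data)) {
    data <- dplyr::mutate(data, seq = dplyr::row_number(), .by = "route_id")
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$seq, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$route_id), scales = "free") +
    ggplot2::labs(x = "observation", y = "PM2.5 (mg/m3)")
  if (!is.null(window)) {
    sm <- smooth_routes(data[c("route_id", "seq", "value")], window)
    p <- p + ggplot2::geom_line(data = sm, colour = "firebrick",
                                linewidth = 0.5)
  }
  if (!is.null(bands)) {
    cuts <- bands$lower[bands$lower > 0 & is.finite(bands$lower)]
    p <- p + ggplot2::geom_hline(yintercept = cuts, linetype = "dashed",
                                 colour = "steelblue", linewidth = 0.3)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.pm_trimmed_curve <- function(object, ...) {
  ref <- attr(object, "reference")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$alpha, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$route_id), scales = "free_y") +
    ggplot2::labs(x = "trimming fraction α", y = "location (mg/m3)")
  if (!is.null(ref)) {
    p <- p +
      ggplot2::geom_rect(
        data = ref,
        ggplot2::aes(xmin = -Inf, xmax = Inf,
                     ymin = .data$ci_lower, ymax = .data$ci_upper),
        inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
      ) +
      ggplot2::geom_hline(data = ref,
                          ggplot2::aes(yintercept = .data$median),
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.pm_scale_curves <- function(object, ...) {
  labels <- c(sbi = "biweight S_bi(c)", cn = "subrange C_n(α)")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      family = labels[.data$family])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                   y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$route_id),
                        ggplot2::vars(.data$family), scales = "free") +
    ggplot2::labs(x = "tuning parameter", y = "scale (mg/m3)")
}
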