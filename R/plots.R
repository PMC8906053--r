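# ggplot2 visualisations for the result types. Plots are presentation
# artifacts only; no statistic consumes them.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_segment
#'   geom_col coord_polar scale_x_continuous labs theme_minimal
NULL

#' Plot a fluorescence trace, optionally with detected transients
#'
#' @param object A [trace_record()].
#' @param transients Optional classified transient tibble; peaks are
#'   marked and coloured by spontaneous status.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_record <- function(object, transients = NULL, ...) {
  ch <- trace_channels(object)[1]
  p <- ggplot(object, aes(x = .data$time_s, y = .data[[ch]])) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = ch) +
    theme_minimal()
  if (!is.null(transients) && nrow(transients) > 0) {
    tr <- transients
    tr$status <- dplyr::case_when(
      tr$is_spontaneous %in% TRUE ~ "spontaneous",
      tr$host_excluded ~ "host-excluded",
      .default = "beat")
    yv <- object[[ch]][tr$peak_index]
    p <- p + geom_point(
      data = tibble::tibble(time_s = tr$peak_s, y = yv, status = tr$status),
      aes(x = .data$time_s, y = .data$y, colour = .data$status),
      inherit.aes = FALSE, size = 2) +
      labs(colour = NULL)
  }
  p
}

#' Plot a FRAP curve with its fitted recovery
#'
#' @param object A `frap_fit` (from [fit_recovery()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, ...) {
  cv <- object$curve
  p <- ggplot(cv, aes(x = .data$time_s, y = .data$intensity)) +
    geom_point(size = 0.7, alpha = 0.6) +
    labs(x = "time from bleach (s)", y = "normalized intensity") +
    theme_minimal()
  if (object$n_components > 0) {
    tpred <- seq(0, max(cv$time_s), length.out = 200)
    pred <- object$plateau -
      colSums(object$components$amplitude *
                exp(-outer(object$components$k_per_s, tpred)))
    p <- p + geom_line(data = tibble::tibble(time_s = tpred, intensity = pred),
                       colour = "red")
  }
  p
}

#' Rose plot of striation angles relative to the groove axis
#'
#' Mirrors the usual presentation: 90 degrees = perfect longitudinal
#' alignment in the grooves.
#'
#' @param object An `organization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.organization_result <- function(object, ...) {
  ggplot(object$rose, aes(x = .data$bin_mid_deg, y = .data$count)) +
    geom_col(width = 10, fill = "steelblue", colour = "grey30") +
    coord_polar(start = -pi / 2, direction = -1) +
    scale_x_continuous(limits = c(0, 360),
                       breaks = seq(0, 330, by = 30)) +
    labs(x = "angle relative to groove axis (deg)", y = "windows",
         title = sprintf("organization index = %.2f",
                         object$organization_index)) +
    theme_minimal()
}

#' Quiver plot of a displacement or traction field
#'
#' @param object A `displacement_field` or `traction_field`.
#' @param scale Arrow scale factor (display units per field unit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.displacement_field <- function(object, scale = 10, ...) {
  ggplot(object, aes(x = .data$x_um, y = .data$y_um)) +
    geom_segment(aes(xend = .data$x_um + scale * .data$ux_um,
                     yend = .data$y_um + scale * .data$uy_um),
                 arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
                 linewidth = 0.3) +
    ggplot2::coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' @rdname autoplot.displacement_field
#' @export
autoplot.traction_field <- function(object, scale = 0.05, ...) {
  ggplot(object, aes(x = .data$x_um, y = .data$y_um)) +
    geom_segment(aes(xend = .data$x_um + scale * .data$tx_pa,
                     yend = .data$y_um + scale * .data$ty_pa),
                 arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
                 linewidth = 0.3, colour = "firebrick") +
    ggplot2::coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot a contraction time series (force and displacement)
#'
#' @param object A `contraction_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contraction_series <- function(object, ...) {
  ts <- tidyr::pivot_longer(object$timeseries,
                            c("total_force_nn", "mean_displacement_um"),
                            names_to = "quantity", values_to = "value")
  ggplot(ts, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}
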