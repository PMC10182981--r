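#' Plot an H&E tile
#'
#' Renders the RGB raster with axes in microns.
#'
#' @param tile an [he_tile].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_tile <- function(tile, ...) {
  d <- dim(tile$rgb)
  mpp <- tile$microns_per_pixel
  hex <- grDevices::rgb(tile$rgb[, , 1], tile$rgb[, , 2], tile$rgb[, , 3],
                        maxColorValue = 255)
  df <- tibble::tibble(
    x = rep((seq_len(d[2]) - 0.5) * mpp, each = d[1]),
    y = rep((seq_len(d[1]) - 0.5) * mpp, times = d[2]),
    fill = as.vector(hex))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @describeIn tils_roc ROC curve plot with the chance diagonal.
#' @param object a `tils_roc` object (for `autoplot`).
#' @export
autoplot.tils_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f)", object$auc,
                      100 * object$conf_level, object$conf_low,
                      object$conf_high)) +
    ggplot2::theme_minimal()
}

#' @describeIn tils_km Kaplan-Meier step curves by group.
#' @param object a `tils_km` object (for `autoplot`).
#' @export
autoplot.tils_km <- function(object, ...) {
  tb <- tidy(object)
  # prepend time 0 / survival 1 per group
  t0 <- dplyr::distinct(tb, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  tb2 <- dplyr::bind_rows(t0, tb[c("group", "time", "survival")])
  p <- ggplot2::ggplot(tb2, ggplot2::aes(.data$time, .data$survival,
                                         colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Event-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$p_value)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-rank p = %.3g", object$p_value))
  }
  p
}

#' Plot detected cells coloured by class
#'
#' Scatter of cell centroids (microns), coloured by assigned class when
#' available.
#'
#' @param object a [cell_set].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cell_set <- function(object, ...) {
  tb <- object$cells
  map <- if ("class" %in% names(tb)) {
    ggplot2::aes(.data$x_um, .data$y_um, colour = .data$class)
  } else {
    ggplot2::aes(.data$x_um, .data$y_um)
  }
  ggplot2::ggplot(tb, map) +
    ggplot2::geom_point(ggplot2::aes(size = .data$nucleus_area_um2),
                        alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  size = "nucleus area (µm²)") +
    ggplot2::theme_minimal()
}
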