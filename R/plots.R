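#' Scatter plot of a measure across EOTRH grades
#'
#' The conventional presentation for grade-wise texture measures: one dot
#' per tooth, group mean +/- SD bars, optionally annotated with compact
#' letter display labels from a [compare_groups()] result.
#'
#' @param features Feature tibble from [extract_features()].
#' @param measure,filter Which combination to plot.
#' @param comparison Optional `grade_comparison` whose letters are drawn
#'   above each group.
#' @return A ggplot object.
#' @export
plot_measure_by_grade <- function(features, measure, filter,
                                  comparison = NULL) {
  sub <- features[features$measure == measure &
                    features$filter == filter &
                    is.finite(features$value), ]
  summ <- sub |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = factor(.data$grade),
                                         y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_errorbar(
      data = summ,
      ggplot2::aes(x = factor(.data$grade), y = .data$mean,
                   ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.3, linewidth = 0.7) +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(x = factor(.data$grade),
                                     y = .data$mean),
                        shape = 3, size = 2) +
    ggplot2::labs(x = "EOTRH grade", y = measure,
                  title = paste0(measure, " after ", filter, " filtering")) +
    ggplot2::theme_minimal()
  if (!is.null(comparison)) {
    lab <- comparison$summary
    ymax <- max(sub$value)
    yr <- diff(range(sub$value))
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = factor(.data$group), y = ymax + 0.08 * yr,
                   label = .data$letters),
      inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.grade_comparison <- function(object, ...) {
  summ <- object$summary
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$group),
                                     y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", color = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$sd,
                                    label = .data$letters),
                       vjust = -0.5) +
    ggplot2::labs(x = "group", y = "mean ± SD") +
    ggplot2::theme_minimal()
}

#' Regression similarity plot of two measures across grades
#'
#' Draws both series against numeric grade with their fitted least-squares
#' lines, the visual counterpart of [compare_slopes()].
#'
#' @param series_a,series_b Data frames with columns `grade`, `value`.
#' @param labels Length-2 character vector naming the series.
#' @return A ggplot object.
#' @export
plot_slope_comparison <- function(series_a, series_b,
                                  labels = c("A", "B")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(series_a[c("grade", "value")], series = labels[1]),
    dplyr::mutate(series_b[c("grade", "value")], series = labels[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "EOTRH grade", y = "value") +
    ggplot2::theme_minimal()
}

#' Display a phantom or ROI matrix
#'
#' @param img Numeric intensity matrix.
#' @return A ggplot object (raster heat map in radiographic gray).
#' @export
plot_roi <- function(img) {
  df <- tibble::tibble(
    row = as.vector(row(img)), col = as.vector(col(img)),
    intensity = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
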