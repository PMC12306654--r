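#' Plot a signal profile
#'
#' Line plot of intensity versus position along the sampled line. If a
#' [measure_fwhm()] result is supplied, the baseline, half-height and the two
#' crossings are overlaid.
#'
#' @param object a `profile_measurement`.
#' @param fwhm optional `fwhm_measurement` for the same profile.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot profile_measurement
#' @export
autoplot.profile_measurement <- function(object, fwhm = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along line (mm)", y = "signal intensity") +
    ggplot2::theme_minimal()
  if (!is.null(fwhm) && !is.na(fwhm$fwhm)) {
    p <- p +
      ggplot2::geom_hline(yintercept = fwhm$baseline, linetype = "dotted") +
      ggplot2::geom_hline(yintercept = fwhm$half_height, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = c(fwhm$left_crossing, fwhm$right_crossing),
                          colour = "red", linetype = "dashed") +
      ggplot2::ggtitle(sprintf("FWHM = %.2f mm", fwhm$fwhm))
  }
  p
}

#' Plot a metrics report
#'
#' Condition means with +/- 1 SD error bars for each image-quality measure,
#' grouped by sequence and coloured by processing mode.
#'
#' @param object a `metrics_report` from [build_metrics_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  d <- object$summary
  d$measure <- factor(measure_columns[as.character(d$measure)],
                      levels = unname(measure_columns))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sequence, y = .data$mean,
                                  fill = .data$processing)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- SD across subjects") +
    ggplot2::theme_minimal()
}

#' Display a slice of a volume
#'
#' Quick-look raster of one slice along the third axis of an echo volume,
#' label map or CT-like image, mainly for vignettes and debugging.
#'
#' @param image a `ctlike_image`, `label_map`, `echo_series` (first echo) or
#'   3-D array.
#' @param slice_index slice to show (default: middle slice).
#' @param trim upper quantile at which intensities are clipped for display
#'   (reciprocal-inverted images are dominated by the air cap otherwise).
#' @return A ggplot object.
#' @export
plot_slice <- function(image, slice_index = NULL, trim = 0.99) {
  dat <- if (inherits(image, "label_map")) image$labels
         else if (inherits(image, "echo_series")) image$volumes[[1]]
         else image_data(image)
  slice_index <- slice_index %||% ceiling(dim(dat)[3] / 2)
  sl <- dat[, , slice_index]
  cap <- as.numeric(quantile(sl, trim))
  d <- tidyr::expand_grid(y = seq_len(ncol(sl)), x = seq_len(nrow(sl)))
  d$value <- pmin(as.vector(sl), cap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "SI",
                  title = sprintf("slice %d", slice_index)) +
    ggplot2::theme_minimal()
}
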