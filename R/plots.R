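#' Bland-Altman plot
#'
#' Classic agreement plot: per-pair means against differences, with the
#' mean difference (solid) and the 95% limits of agreement (dashed).
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements (Hct %)",
                  y = "Difference (percentage points)",
                  title = sprintf("Mean difference %.2f, LOA [%.2f, %.2f]",
                                  object$mean_diff, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot a rendered tube sample
#'
#' Displays the raster with the ground-truth marker rows overlaid as
#' horizontal lines (lower, buffy, upper).
#'
#' @param object A `rendered_sample`.
#' @param markers Overlay the truth markers.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rendered_sample <- function(object, markers = TRUE, ...) {
  img <- object$image
  df <- expand.grid(row = seq_len(dim(img)[1]), col = seq_len(dim(img)[2]))
  df$fill <- grDevices::rgb(img[, , 1][as.matrix(df)],
                            img[, , 2][as.matrix(df)],
                            img[, , 3][as.matrix(df)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (markers) {
    m <- object$truth_markers
    p <- p + ggplot2::geom_hline(
      yintercept = c(m$lower_row, m$buffy_row, m$upper_row),
      colour = c("white", "grey80", "grey60"), linewidth = 0.3)
  }
  p
}

#' Dot plot of a validity simulation
#'
#' Grouped dot plot of measured hematocrit by capture condition (plus the
#' simulated mechanical reader), the standard presentation for a
#' method-comparison cohort.
#'
#' @param object A `validity_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validity_simulation <- function(object, ...) {
  meas <- object$measurements
  lev <- c("MHR", names(object$conditions))
  meas$method <- factor(meas$method, levels = lev)
  ggplot2::ggplot(meas, ggplot2::aes(x = .data$method, y = .data$hct_pct)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Hematocrit (%)") +
    ggplot2::theme_minimal()
}
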