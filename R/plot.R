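# ggplot2 display helpers for the main result types.

#' Plot an expression profile
#'
#' Raw red/green/blue/greyscale traces against arc position, with the
#' endoderm-ectoderm boundaries (if known) as vertical lines.
#'
#' @param profile an `expression_profile`.
#' @param channels which traces to draw. Default all four.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, channels = profile_channels) {
  df <- do.call(rbind, lapply(channels, function(ch) {
    data.frame(position = profile$position, value = profile[[ch]], channel = ch)
  }))
  cols <- c(mean_r = "red3", mean_g = "green4", mean_b = "blue3",
            mean_grey = "grey30")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = position, y = value,
                                        color = channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = cols[channels]) +
    ggplot2::labs(x = "cell layer position (px)", y = "expression") +
    ggplot2::theme_minimal()
  bp <- attr(profile, "boundary_positions")
  if (!is.null(bp)) {
    p <- p + ggplot2::geom_vline(xintercept = bp, linetype = "dashed")
  }
  p
}

#' Plot a standardized profile
#'
#' @param profile a `standard_profile`.
#' @return A ggplot object.
#' @export
plot_standard_profile <- function(profile) {
  ggplot2::ggplot(as.data.frame(profile),
                  ggplot2::aes(x = position, y = value)) +
    ggplot2::geom_line(color = "grey20") +
    ggplot2::scale_x_continuous(breaks = seq(-50, 50, 25)) +
    ggplot2::labs(x = "normalized cell layer position", y = "expression (max 100)") +
    ggplot2::theme_minimal()
}

#' Plot an expression landscape
#'
#' Intensity landscape of the angular-slice-by-position array, black (no
#' expression) to bright green (maximum).
#'
#' @param landscape an `expression_landscape`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  grid <- attr(landscape, "grid")
  angles <- attr(landscape, "slice_angles")
  df <- expand.grid(position = grid, slice = angles)
  df$value <- as.vector(t(unclass(landscape)))
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = slice,
                                   fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "green",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "normalized cell layer position",
                  y = "slice angle (degrees)", fill = "expression") +
    ggplot2::theme_minimal()
}
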