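#' Plot class-mean transmission spectra
#'
#' @param tbl A spectrum table.
#' @return A ggplot: mean relative transmittance per class vs wavelength.
#' @export
plot_spectra <- function(tbl) {
  class_mean_spectra(tbl) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$wavelength, y = .data$value, colour = .data$class
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "Relative transmittance (%)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn discrimination_power Discrimination-power profile plot with
#'   the usefulness threshold and above-threshold regions shaded.
#' @param object A `dp_profile`.
#' @param ... Unused.
#' @export
autoplot.dp_profile <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 3
  regions <- select_regions(object, threshold = threshold)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength, y = .data$dp))
  if (nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(
        xmin = .data$start_nm, xmax = .data$end_nm,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Discrimination power") +
    ggplot2::theme_minimal()
}

#' @describeIn topology_search Mean validation accuracy vs hidden-layer
#'   size.
#' @param object An `nhl_search` tibble.
#' @param ... Unused.
#' @export
autoplot.nhl_search <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nhl, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Nodes in hidden layer", y = "Mean validation accuracy (%)"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn sensitivity_analysis Input-importance profile plot.
#' @param object A `sensitivity_profile` tibble.
#' @param ... Unused.
#' @export
autoplot.sensitivity_profile <- function(object, ...) {
  xvar <- if (all(is.finite(object$wavelength))) "wavelength" else "variable"
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[xvar]], y = .data$ratio
  ))
  p <- if (xvar == "wavelength") p + ggplot2::geom_line() else p + ggplot2::geom_col()
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = if (xvar == "wavelength") "Wavelength (nm)" else "Input",
      y = "Error ratio (mean substitution)"
    ) +
    ggplot2::theme_minimal()
}

#' Display an egg mask
#'
#' @param mask An [egg_mask()].
#' @return A ggplot raster of the mask.
#' @export
plot_mask <- function(mask) {
  df <- tidyr::expand_grid(row = seq_len(nrow(mask)), col = seq_len(ncol(mask)))
  df$value <- as.vector(mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "wheat"), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
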