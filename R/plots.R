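# ggplot2 visualisations

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity map
#'
#' Cell map of a classified fishnet: one facet per intensity index, cells
#' filled by Jenks class (no-data cells grey).
#'
#' @param object A `parkscape_map` from [run_mapping()].
#' @param indices Indices to draw (default all classified).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot parkscape_map
#' @export
autoplot.parkscape_map <- function(object,
                                   indices = names(object$breaks), ...) {
  cells <- object$cells
  long <- purrr::map_dfr(indices, function(idx) {
    tibble::tibble(
      index = idx,
      xmin = cells$xmin, xmax = cells$xmax,
      ymin = cells$ymin, ymax = cells$ymax,
      class = factor(cells[[paste0("class_", idx)]])
    )
  })
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$class),
      colour = "white", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_d(na.value = "grey85",
                                  name = "intensity\nclass") +
    ggplot2::facet_wrap(~index) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a correlation screen
#'
#' Feature-by-outcome tile plot of correlation coefficients, with
#' significant cells (p below `alpha`) marked.
#'
#' @param screen Tibble from [correlation_screen()].
#' @param alpha Significance mark threshold (default 0.05).
#' @return A ggplot.
#' @export
plot_correlation_screen <- function(screen, alpha = 0.05) {
  screen <- dplyr::mutate(
    screen,
    feature = factor(.data$feature, levels = rev(landscape_features())),
    sig = !is.na(.data$p.value) & .data$p.value < alpha
  )
  ggplot2::ggplot(screen,
                  ggplot2::aes(x = .data$outcome, y = .data$feature,
                               fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$sig, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  name = "correlation") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model coefficients
#'
#' Dot-and-whisker plot of the term estimates of one or more intensity
#' models (whiskers at +/- 1.96 standard errors where available).
#'
#' @param models Named list of `intensity_model`s.
#' @return A ggplot.
#' @export
plot_model_coefficients <- function(models) {
  df <- model_report(models) |>
    dplyr::filter(.data$term != "(Intercept)")
  has_se <- "std.error" %in% names(df) && !all(is.na(df$std.error))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::labs(x = "estimate (MET-persons per unit fraction)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (has_se) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2)
  }
  p
}
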