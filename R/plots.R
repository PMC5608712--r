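# ggplot2 renderings: elastograms with the blue-to-red modulus scale capped
# at 54 kPa, tracked displacement grids, and the stacked histology model.

.element_polygons <- function(mesh, value) {
  el <- mesh$elements[, 1:3]
  tibble(
    element = rep(seq_len(nrow(el)), each = 3),
    x = as.vector(t(matrix(mesh$nodes[t(el), 1], ncol = 3, byrow = TRUE))),
    y = as.vector(t(matrix(mesh$nodes[t(el), 2], ncol = 3, byrow = TRUE))),
    value = rep(value, each = 3)
  )
}

#' Elastogram plot of a modulus map
#'
#' Renders per-element Young's modulus with the conventional colour coding:
#' zero in blue, the scale maximum (54 kPa by default) in red.
#'
#' @param object a `ve_inversion` or `ve_material`.
#' @param mesh mesh (taken from an inversion object when omitted).
#' @param max_kpa colour-scale maximum, kPa.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ve_inversion
#' @export
autoplot.ve_inversion <- function(object, mesh = NULL, max_kpa = 54, ...) {
  mesh <- mesh %||% object$mesh
  plot_elastogram(object$material, mesh, max_kpa = max_kpa)
}

#' @rdname autoplot.ve_inversion
#' @export
plot_elastogram <- function(object, mesh, max_kpa = 54) {
  E <- unname(object$region_moduli[mesh$region])
  df <- .element_polygons(mesh, E)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$element,
                                   fill = .data$value)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::scale_fill_gradientn(
      colours = c("blue", "cyan", "green", "yellow", "red"),
      limits = c(0, max_kpa), oob = scales_squish, name = "E (kPa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "axial (mm)") +
    ggplot2::theme_minimal()
}

# minimal squish (avoid a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Objective-trajectory plot of an inversion fit
#' @param fit a `ve_inversion`.
#' @return a ggplot of objective vs iteration (log y).
#' @export
plot_convergence <- function(fit) {
  ggplot2::ggplot(fit$trajectory,
                  ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Gauss-Newton iteration", y = "objective") +
    ggplot2::theme_minimal()
}

#' Stacked-disc rendering of the histology surface model
#'
#' @param surface output of [stacked_surface_model()].
#' @return a ggplot showing nested compartment radii along the artery.
#' @export
plot_stacked_model <- function(surface) {
  # draw outer layers first so inner ones stay visible
  surface <- dplyr::mutate(
    surface, compartment = factor(.data$compartment, levels = rev(.compartments)))
  ggplot2::ggplot(surface,
                  ggplot2::aes(.data$station_um, .data$outer_radius_um,
                               fill = .data$compartment)) +
    ggplot2::geom_area(position = "identity") +
    ggplot2::scale_fill_manual(values = .compartment_colors,
                               breaks = .compartments) +
    ggplot2::labs(x = "distance from bifurcation (\u00b5m)",
                  y = "equivalent-circle radius (\u00b5m)") +
    ggplot2::theme_minimal()
}
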