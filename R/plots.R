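#' Plot the endothelial shear stress profile
#'
#' @param object A `wall_shear_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wall_shear_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_mm, y = .data$ess_pa)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "axial position (mm)", y = "endothelial shear stress (Pa)") +
    ggplot2::theme_minimal()
}

#' Plot cross-section areas along the vessel
#'
#' @param object A `cross_sections` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_sections <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("lumen_area_mm2", "wall_area_mm2"),
                            names_to = "area", values_to = "mm2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_mm, y = .data$mm2,
                                   colour = .data$area)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (mm)", y = "area (mm²)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot monthly mean species trajectories
#'
#' @param series The `series` tibble of [simulate_species()] /
#'   [run_plaque_growth()].
#' @param species Character vector of species to show (default all).
#' @return A ggplot, one free-scale facet per species.
#' @export
plot_species_series <- function(series, species = species_names()) {
  df <- tidyr::pivot_longer(series, dplyr::any_of(species),
                            names_to = "species", values_to = "mean")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$mean)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "month", y = "wall mean concentration") +
    ggplot2::theme_minimal()
}

#' Plot baseline and thickened endothelial radius
#'
#' @param object A `growth_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_result <- function(object, ...) {
  df <- tibble::tibble(
    z_mm = rep(object$baseline$z_mm, 2),
    radius_mm = c(endothelium_radius(object$baseline),
                  endothelium_radius(object$deformed)),
    geometry = rep(c("baseline", "deformed"),
                   each = length(object$baseline$z_mm))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_mm, y = .data$radius_mm,
                                   colour = .data$geometry)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (mm)", y = "endothelial radius (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
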