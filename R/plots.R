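# ggplot2 views of meshes, temperature fields and sensor traces.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sensor traces of a scenario result
#'
#' @param object An `mwa_scenario_result`.
#' @param ... Unused.
#' @return A ggplot: temperature versus time per sensor, with the 60 deg C
#'   ablation threshold marked.
#' @method autoplot mwa_scenario_result
#' @export
autoplot.mwa_scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time, y = .data$temperature,
                               colour = .data$sensor)) +
    ggplot2::geom_hline(yintercept = 60, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "temperature (°C)", colour = "sensor",
      title = sprintf("%g W for %g s, insertion %.1f cm (%s)",
                      object$config$input_power, object$config$heating_duration,
                      object$config$insertion_depth * 100, object$config$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a temperature field on the mirrored cross section
#'
#' @param object An `mwa_temperature`.
#' @param time_index Column of the time series to draw (default: final).
#' @param mirror Draw the full mirrored cross section (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot of per-element temperature on the (r, z) plane in mm.
#' @method autoplot mwa_temperature
#' @export
autoplot.mwa_temperature <- function(object, time_index = NULL, mirror = TRUE, ...) {
  mesh <- object$mesh
  ti <- time_index %||% ncol(object$values)
  Tn <- object$values[, ti]
  tri <- mesh$tri
  df <- tibble::tibble(
    id = rep(seq_len(nrow(tri)), each = 3),
    r = mesh$nodes[as.vector(t(tri)), 1],
    z = mesh$nodes[as.vector(t(tri)), 2],
    temperature = rep((Tn[tri[, 1]] + Tn[tri[, 2]] + Tn[tri[, 3]]) / 3, each = 3))
  if (mirror) {
    df <- dplyr::bind_rows(df, dplyr::mutate(df, r = -.data$r,
                                             id = .data$id + max(df$id)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1e3, y = .data$z * 1e3,
                                   group = .data$id, fill = .data$temperature)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "depth (mm)", fill = "T (°C)") +
    ggplot2::theme_minimal()
}

#' Plot a mesh with region colouring
#'
#' @param mesh An `mwa_mesh`.
#' @return A ggplot of the triangulation in mm.
#' @export
plot_mesh <- function(mesh) {
  tri <- mesh$tri
  df <- tibble::tibble(
    id = rep(seq_len(nrow(tri)), each = 3),
    r = mesh$nodes[as.vector(t(tri)), 1],
    z = mesh$nodes[as.vector(t(tri)), 2],
    region = rep(mesh$region, each = 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1e3, y = .data$z * 1e3,
                                   group = .data$id, fill = .data$region)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.05) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (mm)", y = "depth (mm)") +
    ggplot2::theme_minimal()
}
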