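# ggplot2 views of the result objects. Matrices are melted to long tibbles
# with physical coordinates so maps plot on micrometre axes.

map_to_tibble <- function(mat, pixel_size_um, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(mat)), times = ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat)
  ) |>
    dplyr::mutate(x_um = (.data$col - 1) * pixel_size_um,
                  y_um = (.data$row - 1) * pixel_size_um) |>
    dplyr::rename(!!value_name := "value")
}

#' Plot the calibration curves of a depth LUT
#'
#' One metric-vs-depth curve per subregion; the spread between curves
#' visualises the field-dependent aberration the sub-region calibration
#' absorbs.
#'
#' @param object A `depth_lut`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_lut <- function(object, ...) {
  df <- dplyr::mutate(object$samples,
                      subregion = paste0(.data$sub_row, ",", .data$sub_col))
  ggplot2::ggplot(df, ggplot2::aes(.data$z_um, .data$value,
                                   group = .data$subregion,
                                   colour = .data$subregion)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "depth z (µm)", y = object$metric,
                  colour = "subregion") +
    ggplot2::theme_minimal()
}

#' Plot rendered SL maps
#'
#' @param object A `rendered_maps` result.
#' @param which `"depth"`, `"velocity"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rendered_maps <- function(object, which = "depth", ...) {
  which <- match.arg(which, c("depth", "velocity", "density"))
  mat <- switch(which, depth = object$depth_um,
                velocity = object$speed_mm_s, density = object$counts)
  lab <- switch(which, depth = "depth (µm)",
                velocity = "speed (mm/s)", density = "counts")
  df <- map_to_tibble(mat, object$pixel_size_um)
  df <- df[!is.na(df$value) & (which != "density" | df$value > 0), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a compounded MI volume
#'
#' @param object A `compounded_volume`.
#' @param which `"depth"` or `"intensity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compounded_volume <- function(object, which = "depth", ...) {
  which <- match.arg(which, c("depth", "intensity"))
  mat <- if (which == "depth") object$depth_um else object$intensity
  df <- map_to_tibble(mat, object$pixel_size_um)
  df <- df[!is.na(df$value) & (which != "intensity" | df$value > 0), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      name = if (which == "depth") "depth (µm)" else "counts") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a time-to-peak map
#'
#' @param object A `ttp_map`.
#' @param pixel_size_um Pixel pitch for the axes (um).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ttp_map <- function(object, pixel_size_um = 1, ...) {
  df <- map_to_tibble(object$ttp_s, pixel_size_um)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "TTP (s)", option = "plasma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
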