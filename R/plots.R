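utils::globalVariables(c("centre_deg", "frequency", "x", "y", "value",
                         "zone", "day", "air_max", "soil_max", "group"))

# long tibble of one ny x nx field with cell-centre coordinates
field_tibble <- function(field, grid) {
  tibble::tibble(
    x = rep(cell_centres_x(grid), each = grid$ny),
    y = rep(cell_centres_y(grid), times = grid$nx),
    value = as.vector(field)
  )
}

#' Plot a wind rose
#'
#' @param rose A [wind_rose()] table.
#' @return A ggplot object.
#' @export
plot_wind_rose <- function(rose) {
  width <- 360 / nrow(rose)
  ggplot2::ggplot(rose, ggplot2::aes(x = centre_deg, y = frequency)) +
    ggplot2::geom_col(width = width * 0.9, fill = "steelblue") +
    ggplot2::coord_polar(start = -width / 2 * pi / 180) +
    ggplot2::scale_x_continuous(limits = c(-width / 2, 360 - width / 2),
                                breaks = c(0, 90, 180, 270),
                                labels = c("N", "E", "S", "W")) +
    ggplot2::labs(x = NULL, y = "frequency",
                  title = "Wind direction frequency (blowing from)") +
    ggplot2::theme_minimal()
}

#' Map one day of a simulated concentration field
#'
#' @param object A `concentration_history`.
#' @param day Day to draw.
#' @param medium `"air"` (mg/m^3) or `"soil"` (mg/kg).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_history
#' @export
autoplot.concentration_history <- function(object, day = 1,
                                           medium = c("air", "soil"), ...) {
  medium <- match.arg(medium)
  f <- if (medium == "air") object$air_daily[, , day] else object$soil_daily[, , day]
  df <- field_tibble(f, object$grid)
  src <- source_xy(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      trans = "sqrt",
      name = if (medium == "air") "mg/m³" else "mg/kg") +
    ggplot2::annotate("point", x = src[1], y = src[2], shape = 4,
                      colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s concentration, day %d", medium, day),
                  x = "east (m)", y = "north (m)") +
    ggplot2::theme_minimal()
}

#' Map risk zones or ECR per age group
#'
#' @param object A `risk_assessment`.
#' @param what `"zones"` for the red/orange/green classification,
#'   `"ecr"` for the continuous risk surface.
#' @param ... Unused.
#' @return A ggplot object faceted by age group.
#' @method autoplot risk_assessment
#' @export
autoplot.risk_assessment <- function(object, what = c("zones", "ecr"), ...) {
  what <- match.arg(what)
  df <- purrr::list_rbind(purrr::map(object$maps, function(m) {
    d <- field_tibble(m$ecr, object$grid)
    d$zone <- as.vector(m$zones)
    d$group <- m$group
    d
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x, y)) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "east (m)", y = "north (m)") +
    ggplot2::theme_minimal()
  if (what == "zones") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = zone)) +
      ggplot2::scale_fill_manual(values = c(red = "#d7191c",
                                            orange = "#fdae61",
                                            green = "#a6d96a")) +
      ggplot2::labs(title = "Excess cancer risk zones")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = value)) +
      ggplot2::scale_fill_viridis_c(trans = "sqrt", name = "ECR") +
      ggplot2::labs(title = "Excess cancer risk")
  }
}

#' Daily grid-wide maxima of air and soil concentration
#'
#' @param object A `concentration_history`.
#' @param ... Unused.
#' @return A ggplot object with both media on log scale.
#' @export
autoplot_daily_extrema <- function(object, ...) {
  ex <- daily_extrema(object)
  df <- tidyr::pivot_longer(ex[, c("day", "air_max", "soil_max")],
                            -day, names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(day, value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day since release", y = "grid maximum",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
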