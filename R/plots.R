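#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map view of the landscape at one time step
#'
#' Elevation (or temperature) raster with the coastline implied by the
#' suitability mask.
#'
#' @param object an `isle_landscape`.
#' @param step time step to draw.
#' @param layer `"elevation"`, `"tmin"` or `"tmax"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot isle_landscape
#' @export
autoplot.isle_landscape <- function(object, step = object$config$n_steps,
                                    layer = c("elevation", "tmin", "tmax"),
                                    ...) {
  layer <- match.arg(layer)
  elev <- elevation_grid(object, step)
  val <- switch(layer,
    elevation = elev,
    tmin = site_temperatures(object, step, elev)$tmin,
    tmax = site_temperatures(object, step, elev)$tmax
  )
  suit <- elev > object$manifest$sea_level[step]
  df <- tibble::tibble(
    x = as.vector(row(val)),
    y = as.vector(col(val)),
    value = as.vector(val),
    land = as.vector(suit)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = df[df$land, ], shape = ".", colour = "black",
                        alpha = 0.4) +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s at %.2f Ma (sea level %.1f m)", layer,
                      object$manifest$time_ma[step],
                      object$manifest$sea_level[step]),
      x = "km", y = "km"
    )
}

#' Time series of a simulation run
#'
#' Species richness and total occupied area through time.
#'
#' @param object an `isle_sim`.
#' @param ... unused.
#' @method autoplot isle_sim
#' @export
autoplot.isle_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series,
                            c("n_species", "n_populations"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time step (10 kyr)", y = NULL,
                  title = sprintf("model %s, d = %.2f, l = %.2f",
                                  object$config$model, object$config$d_init,
                                  object$config$l_init))
}

#' Dispersal-gradient curves of an experiment
#'
#' Mean metric per initial dispersal value, one line per tolerance level,
#' with the connectivity-regime boundaries marked.
#'
#' @param object an `isle_experiment`.
#' @param metric column to plot (default `"gamma"`).
#' @param ... unused.
#' @method autoplot isle_experiment
#' @export
autoplot.isle_experiment <- function(object, metric = "gamma", ...) {
  cells <- experiment_cells(object)
  ggplot2::ggplot(cells, ggplot2::aes(.data$d_init, .data[[metric]],
                                      colour = factor(.data$l_init),
                                      linetype = .data$model)) +
    ggplot2::geom_vline(xintercept = c(0.15, 0.55), colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "initial dispersal trait d", y = metric,
                  colour = "tolerance l", linetype = "model")
}
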