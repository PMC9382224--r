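#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_ribbon
#'   scale_fill_viridis_c labs theme_minimal geom_segment
#' @export
ggplot2::autoplot

#' Plot an FTLE field
#'
#' Raster map of the FTLE grid (day^-1); masked cells are blank.
#'
#' @param object An `ftle_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ftle_field
#' @export
autoplot.ftle_field <- function(object, ...) {
  d <- as_tibble(object)
  d$ftle[!d$valid] <- NA_real_
  ggplot(d, aes(.data$lon, .data$lat, fill = .data$ftle)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(FTLE ~ (day^-1)), na.value = "grey90") +
    labs(x = if (object$planar) "x (km)" else "longitude",
         y = if (object$planar) "y (km)" else "latitude",
         title = sprintf("Backward FTLE, t = %g h (horizon %g h)",
                         object$time, object$horizon)) +
    theme_minimal()
}

#' Quiver plot of a velocity field frame
#'
#' @param object A `velocity_field`.
#' @param frame Frame index to draw (default 1).
#' @param skip Draw every `skip`-th node to declutter.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, frame = 1, skip = 1, ...) {
  d <- as_tibble(object)
  d <- d[d$time == object$time[frame], ]
  keep_lon <- object$lon[seq(1, length(object$lon), by = skip)]
  keep_lat <- object$lat[seq(1, length(object$lat), by = skip)]
  d <- d[d$lon %in% keep_lon & d$lat %in% keep_lat & !d$land, ]
  sc <- 0.4 * min(diff(object$lon)[1], diff(object$lat)[1]) /
    max(sqrt(d$u^2 + d$v^2), na.rm = TRUE)
  ggplot(d, aes(.data$lon, .data$lat)) +
    geom_segment(aes(xend = .data$lon + sc * .data$u,
                     yend = .data$lat + sc * .data$v),
                 arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
                 na.rm = TRUE) +
    labs(x = if (object$planar) "x (km)" else "longitude",
         y = if (object$planar) "y (km)" else "latitude",
         title = sprintf("Surface currents, t = %g h", object$time[frame])) +
    theme_minimal()
}

#' Plot a stationary feeding-rate curve
#'
#' Estimated overall feeding rate against FTLE with the confidence band
#' from the transition-coefficient interval endpoints.
#'
#' @param object A `stationary_curve` from [estimate_feeding_rate_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stationary_curve
#' @export
autoplot.stationary_curve <- function(object, ...) {
  ggplot(object, aes(.data$x, .data$rate)) +
    geom_ribbon(aes(ymin = .data$rate_lo, ymax = .data$rate_hi),
                fill = "steelblue", alpha = 0.25) +
    geom_line(linewidth = 0.8) +
    labs(x = expression(FTLE ~ (day^-1)),
         y = expression(estimated ~ feeding ~ rate ~ (lunges ~ h^-1))) +
    theme_minimal()
}

#' Plot stationary state probabilities against FTLE
#'
#' @param curve A `stationary_curve`.
#' @return A ggplot with one line per behavioural state.
#' @export
plot_state_probabilities <- function(curve) {
  d <- tidyr::pivot_longer(as_tibble(curve),
                           dplyr::starts_with("pi_"),
                           names_to = "state", values_to = "pi",
                           names_prefix = "pi_")
  d$state <- factor(d$state, levels = c("nonfeeding", "light", "moderate", "heavy"))
  ggplot(d, aes(.data$x, .data$pi, colour = .data$state)) +
    geom_line(linewidth = 0.8) +
    labs(x = expression(FTLE ~ (day^-1)), y = "stationary probability",
         colour = "state") +
    theme_minimal()
}
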