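# ggplot2 diagnostics for the main result types.

#' Plot a velocity profile with segment boundaries
#'
#' @param profile A [compute_velocity()] profile.
#' @param segmented Optional [segment_trial()] result; segment boundaries
#'   are drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_velocity_profile <- function(profile, segmented = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$t, .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "speed (cm/s)")
  if (!is.null(segmented)) {
    bounds <- profile$t[segmented$segments$end_idx]
    p <- p + ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot sliding-window radial distance over training
#'
#' @param rd A [radial_distance()] table.
#' @return A ggplot object: per-window mean RD% against window start trial.
#' @export
plot_radial_distance <- function(rd) {
  means <- dplyr::distinct(rd, .data$window_start_trial, .data$rd_mean)
  ggplot2::ggplot(means,
                  ggplot2::aes(.data$window_start_trial, .data$rd_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "window start trial", y = "radial distance (%)")
}

#' @describeIn bootstrap_fit Group mean with the fitted curve and a
#'   pointwise 95% band from the bootstrap draws.
#' @export
autoplot.bootstrap_fit <- function(object, ...) {
  gm <- object$group_mean
  xs <- gm$trial
  pred <- purrr::pmap(object$draws, function(draw, r_squared, ...) {
    pars <- list(...)
    predict_family(object$family, pars, xs)
  })
  mat <- do.call(cbind, pred)
  band <- tibble(
    trial = xs,
    fit = predict_family(object$family,
                         as.list(object$estimate), xs),
    lower = apply(mat, 1L, quantile, 0.025),
    upper = apply(mat, 1L, quantile, 0.975)
  )
  ggplot2::ggplot(gm, ggplot2::aes(.data$trial, .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(.data$trial, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.25) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(.data$trial, .data$fit),
                       inherit.aes = FALSE, colour = "firebrick") +
    ggplot2::labs(x = "trial", y = "group mean",
                  title = sprintf("%s bootstrap fit", object$family))
}

#' @describeIn piecewise_fit Scatter with the fitted hinge function.
#' @export
autoplot.piecewise_fit <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  xs <- seq(min(object$x), max(object$x), length.out = 200L)
  line <- tibble(x = xs, y = predict(object, xs))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$knot, linetype = "dashed") +
    ggplot2::labs(x = "fusion index", y = "radial distance (%)")
}
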