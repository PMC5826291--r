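# ggplot2 autoplot methods for the package's result types.

#' @export
autoplot.radial_profile <- function(object, slices = FALSE, ...) {
  if (slices) {
    ggplot(object$slices, aes(x = .data$r, y = .data$density,
                              group = .data$z, colour = .data$z)) +
      geom_line(alpha = 0.6) +
      labs(x = "r (nm)", y = "density (mg/ml)", colour = "z (nm)",
           title = sprintf("Radial density, window '%s'", object$window)) +
      theme_minimal()
  } else {
    ggplot(object$profile, aes(x = .data$r, y = .data$density)) +
      geom_line(linewidth = 0.8) +
      labs(x = "r (nm)", y = "density (mg/ml)",
           title = sprintf("Radial density, window '%s'", object$window)) +
      theme_minimal()
  }
}

#' @export
autoplot.density_rz <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$z, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c(name = "mg/ml") +
    labs(x = "r (nm)", y = "z (nm)", title = "(r, z) density map") +
    theme_minimal()
}

#' @export
autoplot.conductance_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$diameter, y = .data$G)) +
    geom_line(linewidth = 0.8) +
    labs(x = "pore diameter (nm)", y = "conductance (nS)",
         title = "Closed-form conductance curve") +
    theme_minimal()
}

#' @export
autoplot.pmf_curve <- function(object, smooth = TRUE, ...) {
  p <- ggplot(object$profile, aes(x = .data$z, y = .data$pmf)) +
    geom_point(size = 0.8, alpha = 0.6) +
    labs(x = "z (nm)", y = "PMF (kJ/mol)",
         title = "Potential of mean force along the pore axis") +
    theme_minimal()
  if (smooth) {
    p <- p + geom_line(data = smooth_pmf(object), colour = "firebrick")
  }
  p
}

#' @export
autoplot.current_trace <- function(object, events = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time, y = .data$current)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = "current (nA)") +
    theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + geom_segment(
      data = events,
      aes(x = .data$start, xend = .data$start + .data$dwell),
      y = min(object$current), yend = min(object$current),
      colour = "firebrick", linewidth = 1.5, inherit.aes = FALSE
    )
  }
  p
}

#' @export
autoplot.event_table <- function(object, ...) {
  ggplot(object, aes(x = .data$dwell * 1000, y = .data$blockade)) +
    geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    labs(x = "dwell time (ms)", y = "conductance blockade (nS)",
         title = "Translocation events") +
    theme_minimal()
}
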