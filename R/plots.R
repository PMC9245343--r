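#' Plot a current trace
#'
#' @param object A `current_trace` (or spike) tibble.
#' @param ... Unused.
#' @return A ggplot: current (pA) versus time (ms).
#' @method autoplot current_trace
#' @export
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time * 1e3, y = .data$current * 1e12)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (ms)", y = "current (pA)")
}

#' @rdname autoplot.current_trace
#' @method autoplot spike
#' @export
autoplot.spike <- function(object, ...) {
  autoplot.current_trace(object, ...)
}

#' Plot a pore-radius trajectory
#'
#' @param object A `pore_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot: pore radius (nm) versus time (ms), coloured by flag
#'   when a `flag` column is present.
#' @method autoplot pore_trajectory
#' @export
autoplot.pore_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time * 1e3, y = .data$radius * 1e9))
  if ("flag" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$flag), size = 1)
  } else {
    p <- p + ggplot2::geom_line(colour = "#d95f02")
  }
  p + ggplot2::labs(x = "time (ms)", y = "pore radius (nm)")
}

#' Plot a reconstruction: fitted trajectory and current fit
#'
#' @param object A `pore_reconstruction`.
#' @param ... Unused.
#' @return A ggplot of the reconstructed radius knots (nm, coloured by
#'   flag) over time (ms).
#' @method autoplot pore_reconstruction
#' @export
autoplot.pore_reconstruction <- function(object, ...) {
  autoplot.pore_trajectory(object$steps[c("time", "radius", "flag")]) +
    ggplot2::labs(
    title = sprintf(
      "R_p,max = %.1f nm, t_expa = %.2f ms",
      object$r_p_max * 1e9, object$t_expa * 1e3
    )
  )
}

#' Plot a log-log scaling fit over its data
#'
#' @param object A `loglog_fit`.
#' @param ... Unused.
#' @return A ggplot of log10 pore radius versus log10 vesicle radius with
#'   the fitted line.
#' @method autoplot loglog_fit
#' @export
autoplot.loglog_fit <- function(object, ...) {
  dat <- attr(object, "data")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log10_r_ves, y = .data$log10_r_p_max)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "#d95f02"
    ) +
    ggplot2::labs(
      x = "log10 R_ves (m)", y = "log10 R_p,max (m)",
      title = sprintf(
        "slope %.2f, intercept %.2f, r = %.3f",
        object$slope, object$intercept, object$pearson_r
      )
    )
}
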