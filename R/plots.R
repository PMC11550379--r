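#' Plot a force trace with detected contraction events
#'
#' Quality-control plot: the force-time trace with R peaks (upward
#' triangles) and S peaks (downward triangles) marked when an event table
#' is supplied.
#'
#' @param x A [force_trace()].
#' @param events Optional `contraction_events` data frame from
#'   [detect_events()].
#' @param xlim Optional time window in seconds.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.force_trace <- function(x, events = NULL, xlim = NULL, ...) {
  sel <- if (is.null(xlim)) TRUE else x$t >= xlim[1] & x$t <= xlim[2]
  graphics::plot(x$t[sel], x$f[sel], type = "l", xlab = "time (s)",
                 ylab = "force (nN)", ...)
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- events
    if (!is.null(xlim)) ev <- ev[ev$t_R >= xlim[1] & ev$t_R <= xlim[2], ]
    graphics::points(ev$t_R, ev$f_R, pch = 24, bg = "firebrick")
    graphics::points(ev$t_S, ev$f_S, pch = 25, bg = "steelblue")
  }
  invisible(x)
}

#' Poincare plot of a BRV result
#'
#' Scatter of successive RR pairs `(RR[i], RR[i+1])` with the identity
#' line; the SD1/SD2 ellipse axes summarise short- and long-term beat-rate
#' variability.
#'
#' @param x A `brv_result` from [brv()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.brv_result <- function(x, ...) {
  p <- x$poincare_pairs
  if (nrow(p) == 0L) {
    stop("plot.brv_result: no Poincare pairs to plot", call. = FALSE)
  }
  lim <- range(p)
  graphics::plot(p[, 1], p[, 2], xlab = "RR[i] (s)", ylab = "RR[i+1] (s)",
                 xlim = lim, ylim = lim, pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  m <- mean(p)
  if (is.finite(x$sd1_s) && is.finite(x$sd2_s)) {
    graphics::arrows(m - x$sd2_s / sqrt(2), m - x$sd2_s / sqrt(2),
                     m + x$sd2_s / sqrt(2), m + x$sd2_s / sqrt(2),
                     length = 0.05, code = 3, col = "firebrick")
    graphics::arrows(m + x$sd1_s / sqrt(2), m - x$sd1_s / sqrt(2),
                     m - x$sd1_s / sqrt(2), m + x$sd1_s / sqrt(2),
                     length = 0.05, code = 3, col = "darkorange")
  }
  invisible(x)
}

#' Residual plot for a dose-response fit
#'
#' @param x A [dose_slope()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dose_slope <- function(x, ...) {
  graphics::plot(x$x, x$residuals,
                 xlab = if (x$conc_scale == "log10")
                   "log10 concentration (M)" else "concentration (M)",
                 ylab = "residual", pch = 19, ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
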