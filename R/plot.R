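# Base-graphics views of the main objects.

#' @export
plot.scanner_trace <- function(x, cfg = NULL, show_chi = TRUE, ...) {
  plot(x$time_s, x$position_bp, type = "l", col = "grey40",
       xlab = "time (s)", ylab = "position (bp)",
       main = paste0("translocation trace", if (!is.na(x$variant))
         paste0(" [", x$variant, "]")), ...)
  if (show_chi && !is.null(x$substrate) &&
      length(x$substrate$chi_positions)) {
    graphics::abline(h = range(x$substrate$chi_positions),
                     col = "darkgreen", lty = 3)
  }
  invisible(x)
}

#' @export
plot.chase_series <- function(x, fit = NULL, ...) {
  plot(x$time_min, x$fragment_fraction, pch = 16,
       xlab = "time after chase (min)", ylab = "surviving Chi fragment",
       ylim = c(0, 1.05), ...)
  if (!is.null(fit) && inherits(fit, "decay_fit")) {
    tt <- seq(0, max(x$time_min), length.out = 200)
    graphics::lines(tt, fit$f0 * exp(-fit$k * tt), col = "firebrick")
  }
  invisible(x)
}

#' @export
plot.triplex_curve <- function(x, fit = NULL, ...) {
  plot(x$time_s, x$signal, type = "l",
       xlab = "time (s)", ylab = "normalized triplex displacement", ...)
  if (!is.null(fit) && inherits(fit, "biphasic_fit")) {
    graphics::lines(x$time_s,
                    .biphasic_model(x$time_s, fit$a1, fit$k1, fit$d1,
                                    fit$a2, fit$k2, fit$d2),
                    col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' Plot a velocity-versus-position profile
#'
#' @param profile Output of [mean_velocity_profile()].
#' @param ... Passed to [plot()].
#' @export
plot_velocity_profile <- function(profile, ...) {
  mid <- (profile$bin_start_bp + profile$bin_end_bp) / 2
  plot(mid, profile$mean_velocity, type = "s",
       xlab = "position (bp)", ylab = "mean velocity (bp/s)", ...)
  invisible(profile)
}
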