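#' Plot a root-model solution
#'
#' Tip angle and growth-zone angle against nondimensional time, with the
#' stimulus direction marked.
#'
#' @param object A `root_model_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot root_model_solution
#' @export
autoplot.root_model_solution <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(d[, c("tau", "theta_tip", "k")],
                              cols = c("theta_tip", "k"),
                              names_to = "series", values_to = "angle")
  ggplot2::ggplot(long, ggplot2::aes(.data$tau, .data$angle,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$theta_g,
                        linetype = "dashed") +
    ggplot2::labs(x = expression(tau == dot(epsilon)[0] * t),
                  y = "angle (rad)", colour = NULL)
}

#' Plot a trajectory fit
#'
#' Observed tip angles and the fitted root-model prediction.
#'
#' @param object A `root_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot root_fit
#' @export
autoplot.root_fit <- function(object, ...) {
  d <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.7,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "red") +
    ggplot2::labs(x = "time (h)", y = expression(theta[tip] ~ "(rad)"))
}

#' Plot a curvature kymograph
#'
#' Space-time heat map of curvature; masked cells (beyond the tip) are
#' blank.
#'
#' @param kymo Long kymograph tibble.
#' @return A ggplot object.
#' @export
plot_kymograph <- function(kymo) {
  check_kymograph(kymo)
  ggplot2::ggplot(kymo, ggplot2::aes(.data$time_h, .data$s_mm,
                                     fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (h)", y = "arc length s (mm)",
                  fill = expression(kappa ~ (mm^-1)))
}

#' Plot a shape history
#'
#' Overlays the reconstructed centerlines, coloured by time.
#'
#' @param object A `shape_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_history
#' @export
autoplot.shape_history <- function(object, ...) {
  d <- tidyr::unnest(object$centerlines, "centerline")
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm,
                                  group = .data$time_h,
                                  colour = .data$time_h)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "time (h)")
}
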