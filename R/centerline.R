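#' Planar centerline of an organ
#'
#' A centerline is a tibble with columns `s_mm` (arc length from the base,
#' strictly increasing, mm), `theta` (local tangent angle from the
#' horizontal, radians), and planar coordinates `x_mm`, `y_mm`. Coordinates
#' are reconstructed from the angle profile with [integrate_shape()] unless
#' supplied.
#'
#' @param s Arc-length grid (mm), strictly increasing, `s[1] >= 0`.
#' @param theta Tangent angle at each grid point (radians).
#' @param base_xy Position of the base, length-2 numeric (mm).
#'
#' @return A tibble with columns `s_mm`, `theta`, `x_mm`, `y_mm`.
#' @examples
#' cl <- centerline(seq(0, 1, 0.01), rep(pi / 4, 101))
#' @export
centerline <- function(s, theta, base_xy = c(0, 0)) {
  check_finite(s, "s")
  check_finite(theta, "theta")
  if (length(s) != length(theta)) {
    abort("`s` and `theta` must have the same length.",
          class = "gravitroot_invalid_input")
  }
  if (any(diff(s) <= 0)) {
    abort("`s` must be strictly increasing.",
          class = "gravitroot_invalid_input")
  }
  integrate_shape(theta, s, base_xy = base_xy)
}

#' Local curvature from a tangent-angle profile
#'
#' Curvature is the arc-length derivative of the tangent angle,
#' `kappa = d theta / d s`, evaluated by finite differences (three-point
#' central stencil in the interior, one-sided at the two endpoints) on a
#' possibly non-uniform grid.
#'
#' @param cl A centerline tibble (see [centerline()]), or any data frame with
#'   columns `s_mm` and `theta`; at least 3 rows.
#'
#' @return A tibble with columns `s_mm` and `kappa` (1/mm), on the same grid.
#' @examples
#' cl <- centerline(seq(0, 1, length.out = 200), sin(seq(0, 1, length.out = 200)))
#' curvature_from_angles(cl) # kappa tracks cos(s)
#' @export
curvature_from_angles <- function(cl) {
  if (!all(c("s_mm", "theta") %in% names(cl))) {
    abort("`cl` must have columns `s_mm` and `theta`.",
          class = "gravitroot_invalid_input")
  }
  if (nrow(cl) < 3) {
    abort("Need at least 3 grid points to differentiate.",
          class = "gravitroot_invalid_input")
  }
  tibble(s_mm = cl$s_mm, kappa = fd_gradient(cl$s_mm, cl$theta))
}

#' Integrate a tangent-angle profile into a planar shape
#'
#' Inverse of [curvature_from_angles()] up to the base position: positions
#' are the cumulative trapezoidal integrals of `(cos theta, sin theta)`
#' along arc length.
#'
#' @param theta Tangent angles (radians) on the grid `s`.
#' @param s Arc-length grid (mm), strictly increasing.
#' @param base_xy Base position, length-2 numeric (mm).
#'
#' @return A centerline tibble (`s_mm`, `theta`, `x_mm`, `y_mm`).
#' @examples
#' integrate_shape(rep(pi / 2, 11), seq(0, 1, 0.1)) # vertical segment
#' @export
integrate_shape <- function(theta, s, base_xy = c(0, 0)) {
  check_finite(theta, "theta")
  check_finite(s, "s")
  check_finite(base_xy, "base_xy")
  if (length(s) != length(theta)) {
    abort("`s` and `theta` must have the same length.",
          class = "gravitroot_invalid_input")
  }
  if (any(diff(s) <= 0)) {
    abort("`s` must be strictly increasing.",
          class = "gravitroot_invalid_input")
  }
  x <- base_xy[1] + pracma::cumtrapz(s, cos(theta))[, 1]
  y <- base_xy[2] + pracma::cumtrapz(s, sin(theta))[, 1]
  tibble(s_mm = s, theta = theta, x_mm = x, y_mm = y)
}

#' Locally averaged tangent angle
#'
#' Mean of `theta` over the arc-length window
#' `[s0 - window/2, s0 + window/2]` intersected with the organ, evaluated as
#' a trapezoidal integral (with linear interpolation at the clipped window
#' edges) divided by the window width actually covered. The 0.1 mm default
#' window is the characteristic length used when reading tip and
#' growth-zone-base angles off measured centerlines.
#'
#' @param cl A centerline tibble (columns `s_mm`, `theta`).
#' @param s0 Centre of the averaging window (mm), inside `[0, L]`.
#' @param window Window length (mm), default 0.1.
#'
#' @return The averaged angle (radians).
#' @examples
#' cl <- centerline(seq(0, 1, 0.005), seq(0, 1, 0.005)) # theta(s) = s
#' local_average_angle(cl, 0.5) # 0.5
#' @export
local_average_angle <- function(cl, s0, window = 0.1) {
  check_scalar(s0, "s0")
  check_scalar(window, "window", 0, strict = TRUE)
  s <- cl$s_mm
  theta <- cl$theta
  lo <- max(s0 - window / 2, min(s))
  hi <- min(s0 + window / 2, max(s))
  if (hi <= lo) {
    abort("Averaging window does not intersect the organ.",
          class = "gravitroot_invalid_input")
  }
  if (lo == hi) return(approx(s, theta, xout = lo)$y)
  inside <- s > lo & s < hi
  sg <- c(lo, s[inside], hi)
  tg <- c(approx(s, theta, xout = lo)$y, theta[inside],
          approx(s, theta, xout = hi)$y)
  pracma::trapz(sg, tg) / (hi - lo)
}
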