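#' Sampled tip-angle trajectory
#'
#' Builds and validates the central tabular object of the package: a tibble
#' with one row per imaging time, columns `time_h` (hours, strictly
#' increasing), `theta_tip` (tip angle from the horizontal, radians) and
#' optionally `theta_gz0` (angle at the base of the growth zone, radians)
#' and `length_mm` (organ length, mm).
#'
#' @param time_h Sample times in hours, strictly increasing.
#' @param theta_tip Tip angle at each time, radians.
#' @param theta_gz0 Optional angle at the growth-zone base, radians.
#' @param length_mm Optional organ length at each time, mm.
#'
#' @return A tibble with the validated columns.
#' @examples
#' tip_trajectory(0:10, seq(0, pi / 2, length.out = 11))
#' @export
tip_trajectory <- function(time_h, theta_tip, theta_gz0 = NULL,
                           length_mm = NULL) {
  check_finite(time_h, "time_h")
  check_finite(theta_tip, "theta_tip")
  if (any(diff(time_h) <= 0)) {
    abort("`time_h` must be strictly increasing (duplicated or decreasing timestamps).",
          class = "gravitroot_invalid_input")
  }
  if (length(theta_tip) != length(time_h)) {
    abort("`theta_tip` must have one value per time.",
          class = "gravitroot_invalid_input")
  }
  out <- tibble(time_h = as.numeric(time_h), theta_tip = as.numeric(theta_tip))
  if (!is.null(theta_gz0)) {
    check_finite(theta_gz0, "theta_gz0")
    if (length(theta_gz0) != length(time_h)) {
      abort("`theta_gz0` must have one value per time.",
            class = "gravitroot_invalid_input")
    }
    out$theta_gz0 <- as.numeric(theta_gz0)
  }
  if (!is.null(length_mm)) {
    check_finite(length_mm, "length_mm")
    if (length(length_mm) != length(time_h)) {
      abort("`length_mm` must have one value per time.",
            class = "gravitroot_invalid_input")
    }
    out$length_mm <- as.numeric(length_mm)
  }
  out
}

as_tip_trajectory <- function(df) {
  if (!all(c("time_h", "theta_tip") %in% names(df))) {
    abort("A trajectory needs columns `time_h` and `theta_tip`.",
          class = "gravitroot_invalid_input")
  }
  tip_trajectory(df$time_h, df$theta_tip,
                 theta_gz0 = df[["theta_gz0"]],
                 length_mm = df[["length_mm"]])
}
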