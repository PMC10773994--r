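#' Steady-state tip angle
#'
#' Mean and standard deviation of `theta_tip` over the final window of the
#' record (default: the last 5 h).
#'
#' @param traj A trajectory tibble.
#' @param window Window length in hours (default 5); the record must span
#'   more than this.
#' @return A list with `theta_f` and `sigma` (radians).
#' @export
steady_state_angle <- function(traj, window = 5) {
  traj <- as_tip_trajectory(traj)
  check_scalar(window, "window", 0, strict = TRUE)
  t_end <- max(traj$time_h)
  if (t_end - min(traj$time_h) <= window) {
    abort("Trajectory does not span more than the averaging window.",
          class = "gravitroot_invalid_input")
  }
  last <- traj$theta_tip[traj$time_h >= t_end - window]
  list(theta_f = mean(last), sigma = stats::sd(last))
}

#' Time to gravitropic equilibrium
#'
#' The time for the tip angle to approach its steady-state value
#' `theta_f +/- sigma`. Two readings of "approach" are provided:
#'
#' * `rule = "first_entry"` (default): the first sample falling inside the
#'   band `[theta_f - sigma, theta_f + sigma]`. This is the estimator
#'   consistent with finite equilibrium times on noisy records: with
#'   independent measurement noise of the same scale as `sigma`, individual
#'   late samples keep leaving the band, so any stay-forever criterion
#'   degenerates to the record length.
#' * `rule = "sustained"`: the first time after which *every* subsequent
#'   sample stays inside the band.
#'
#' `sigma` is floored at `sigma_floor` (default 1e-3 rad) so that noiseless
#' synthetic trajectories, whose late-window standard deviation can be
#' arbitrarily small, still define a non-empty band.
#'
#' @param traj A trajectory tibble.
#' @param theta_f,sigma Steady-state angle and its dispersion; computed with
#'   [steady_state_angle()] when omitted.
#' @param sigma_floor Lower bound on the band half-width (radians).
#' @param rule `"first_entry"` or `"sustained"`.
#' @param window Passed to [steady_state_angle()] when needed.
#' @return Equilibrium time in hours. If the band is never entered, the end
#'   of the record is returned with a warning.
#' @export
time_to_equilibrium <- function(traj, theta_f = NULL, sigma = NULL,
                                sigma_floor = 1e-3,
                                rule = c("first_entry", "sustained"),
                                window = 5) {
  traj <- as_tip_trajectory(traj)
  rule <- match.arg(rule)
  if (is.null(theta_f) || is.null(sigma)) {
    ss <- steady_state_angle(traj, window = window)
    theta_f <- theta_f %||% ss$theta_f
    sigma <- sigma %||% ss$sigma
  }
  sigma <- max(sigma, sigma_floor, na.rm = TRUE)
  inside <- abs(traj$theta_tip - theta_f) <= sigma
  idx <- if (rule == "first_entry") {
    which(inside)[1]
  } else {
    out <- which(!inside)
    if (length(out) == 0) 1L else if (max(out) == nrow(traj)) NA_integer_
    else max(out) + 1L
  }
  if (is.na(idx)) {
    warn("Steady-state band never entered; returning the end of the record.")
    return(max(traj$time_h))
  }
  traj$time_h[idx]
}

#' Estimate the growth-zone length from a curvature kymograph
#'
#' The growth zone is the apical region where curvature still changes.
#' The estimator computes the temporal change `dkappa/dt` on the kymograph
#' grid (forward differences, so frozen mature-zone cells are exactly
#' zero), re-indexes each cell by its distance from the tip
#' `d = L(t) - s`, averages `|dkappa/dt|` over times before equilibrium on
#' a uniform distance-from-tip grid, and returns the largest distance at
#' which this tip-frame profile still exceeds `threshold_frac` times its
#' spatial mean. Absolute values are averaged because bending reversals
#' would cancel in a signed mean.
#'
#' @param kymo Long kymograph tibble (`time_h`, `s_mm`, `kappa`,
#'   `length_mm`).
#' @param tau_eq Equilibrium time (hours); only earlier times enter the
#'   average. Requires at least 3 time samples before it.
#' @param threshold_frac Detection threshold as a fraction of the spatial
#'   mean (default 0.05).
#' @param cell Tip-frame grid spacing (mm), default 0.01.
#' @param min_coverage Keep tip-frame cells sampled in at least this
#'   fraction of the retained times (default 0.5).
#' @return A list with `Lgz_mm` (the estimate; `NA` with a warning when no
#'   curvature change is present) and `profile`, the tip-frame tibble
#'   (`dist_mm`, `kdot`).
#' @export
estimate_growth_zone <- function(kymo, tau_eq, threshold_frac = 0.05,
                                 cell = 0.01, min_coverage = 0.5) {
  check_kymograph(kymo)
  if (is.null(kymo[["length_mm"]])) {
    kymo <- dplyr::group_by(kymo, .data$time_h)
    kymo <- dplyr::mutate(kymo, length_mm = max(.data$s_mm))
    kymo <- dplyr::ungroup(kymo)
  }
  check_scalar(tau_eq, "tau_eq", 0)
  times <- sort(unique(kymo$time_h))
  times <- times[times < tau_eq]
  if (length(times) < 3) {
    abort("Need at least 3 kymograph times before `tau_eq`.",
          class = "gravitroot_invalid_input")
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(kymo, .data$time_h %in% times),
    id_cols = "s_mm", names_from = "time_h", values_from = "kappa"
  )
  wide <- dplyr::arrange(wide, .data$s_mm)
  s_grid <- wide$s_mm
  kap <- as.matrix(wide[, -1, drop = FALSE])
  kap <- kap[, order(as.numeric(colnames(kap))), drop = FALSE]
  L_of_t <- vapply(times, function(t) {
    max(kymo$length_mm[kymo$time_h == t])
  }, numeric(1))
  # forward difference in time at fixed s, assigned to the earlier time
  nt <- length(times)
  d_grid <- seq(0, max(L_of_t), by = cell)
  acc <- matrix(NA_real_, nrow = length(d_grid), ncol = nt - 1)
  for (j in seq_len(nt - 1)) {
    dt <- times[j + 1] - times[j]
    kdot <- abs(kap[, j + 1] - kap[, j]) / dt
    ok <- !is.na(kdot)
    if (sum(ok) < 2) next
    d <- L_of_t[j] - s_grid[ok]
    o <- order(d)
    acc[, j] <- approx(d[o], kdot[ok][o], xout = d_grid, rule = 1)$y
  }
  coverage <- rowMeans(!is.na(acc))
  keep <- coverage >= min_coverage
  profile <- tibble(
    dist_mm = d_grid[keep],
    kdot = rowMeans(acc[keep, , drop = FALSE], na.rm = TRUE)
  )
  scale <- max(profile$kdot, 0)
  if (scale <= 1e-12) {
    warn("No curvature change in the kymograph: growth zone undefined.")
    return(list(Lgz_mm = NA_real_, profile = profile))
  }
  thr <- threshold_frac * mean(profile$kdot)
  above <- which(profile$kdot > thr)
  list(Lgz_mm = profile$dist_mm[max(above)], profile = profile)
}

#' Compare an observed and a modelled centerline
#'
#' Resamples both shapes on a common arc-length grid from the base
#' (truncated to the shorter organ) and reports two scores: the mean
#' point-to-point Euclidean distance normalised by the organ radius, and
#' the mean absolute tangent-angle difference in degrees. Identical shapes
#' score (0, 0); the angle score is invariant to joint translation and the
#' distance score to joint rotation.
#'
#' @param exp_shape,model_shape Centerline tibbles (see [centerline()]).
#' @param radius Organ radius (mm) used to normalise distances.
#' @param grid_step Comparison grid spacing (mm), default 0.01.
#' @param max_length_mismatch Maximal tolerated relative difference in total
#'   arc length (default 0.1).
#' @return A list with `dist_score` (dimensionless) and `angle_score`
#'   (degrees).
#' @export
shape_scores <- function(exp_shape, model_shape, radius, grid_step = 0.01,
                         max_length_mismatch = 0.1) {
  check_scalar(radius, "radius", 0, strict = TRUE)
  L1 <- max(exp_shape$s_mm)
  L2 <- max(model_shape$s_mm)
  if (abs(L1 - L2) > max_length_mismatch * max(L1, L2)) {
    abort("Arc lengths differ by more than 10%: comparison is ill-defined.",
          class = "gravitroot_invalid_input")
  }
  sg <- seq(0, min(L1, L2), by = grid_step)
  f <- function(shape, col) approx(shape$s_mm, shape[[col]], xout = sg)$y
  dx <- f(exp_shape, "x_mm") - f(model_shape, "x_mm")
  dy <- f(exp_shape, "y_mm") - f(model_shape, "y_mm")
  dth <- f(exp_shape, "theta") - f(model_shape, "theta")
  list(
    dist_score = mean(sqrt(dx^2 + dy^2)) / radius,
    angle_score = mean(abs(dth)) * 180 / pi
  )
}

#' One-row summary of a gravitropic response
#'
#' Convenience wrapper combining [steady_state_angle()],
#' [time_to_equilibrium()] and optionally [estimate_growth_zone()] into one
#' tidy row, including the nondimensional response duration
#' `eps0 * tau_eq` (the growth during the response in units of the
#' growth-zone length).
#'
#' @param traj A trajectory tibble.
#' @param geometry Optional [organ_geometry()] (for `eps0`).
#' @param kymo Optional kymograph for the growth-zone estimate.
#' @param window Steady-state window (hours).
#' @param ... Passed to [time_to_equilibrium()].
#' @return A one-row tibble with `theta_f`, `sigma_theta_f`, `tau_eq_h`,
#'   `nd_growth`, `Lgz_mm`.
#' @export
response_summary <- function(traj, geometry = NULL, kymo = NULL, window = 5,
                             ...) {
  ss <- steady_state_angle(traj, window = window)
  tau_eq <- time_to_equilibrium(traj, theta_f = ss$theta_f, sigma = ss$sigma,
                                ...)
  lgz <- if (!is.null(kymo)) {
    estimate_growth_zone(kymo, tau_eq)$Lgz_mm
  } else {
    NA_real_
  }
  tibble(
    theta_f = ss$theta_f, sigma_theta_f = ss$sigma, tau_eq_h = tau_eq,
    nd_growth = if (!is.null(geometry)) geometry$growth_rate * tau_eq else NA_real_,
    Lgz_mm = lgz
  )
}
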