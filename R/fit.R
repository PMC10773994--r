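#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, the screening statistic used to accept
#' trajectory fits. Degenerate inputs with zero total sum of squares have no
#' defined `R^2`; the function then returns `NA` with a warning.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single number (or `NA` for degenerate input).
#' @examples
#' r_squared(c(0, 1, 2), c(0.1, 1.0, 1.9)) # 0.99
#' @export
r_squared <- function(observed, predicted) {
  check_finite(observed, "observed")
  check_finite(predicted, "predicted")
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.",
          class = "gravitroot_invalid_input")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("Constant observations: R^2 is undefined.")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Tip growth velocity from organ lengths
#'
#' Ordinary least-squares slope of `L(t)`, the linear-growth estimate of the
#' tip velocity `v_g`.
#'
#' @param time_h Times (hours), at least 3.
#' @param length_mm Organ lengths (mm).
#' @return Slope in mm/h.
#' @export
growth_velocity <- function(time_h, length_mm) {
  check_finite(time_h, "time_h")
  check_finite(length_mm, "length_mm")
  if (length(time_h) < 3 || length(length_mm) != length(time_h)) {
    abort("Need >= 3 (time, length) pairs.",
          class = "gravitroot_invalid_input")
  }
  unname(coef(lm(length_mm ~ time_h))[2])
}

#' Box bounds for trajectory fitting
#'
#' The physically meaningful region explored by the optimiser. Only
#' `theta0 > 0` is imposed by the identifiability argument (both
#' `theta0 - theta_g` and `-theta0 - theta_g` give the same initial
#' condition for a horizontal tilt); the remaining bounds keep the search
#' inside the plausible range while covering all reported estimates.
#'
#' @param gamma,eta,theta0 Length-2 numeric `(lower, upper)` for each
#'   parameter.
#' @return A named list of bounds.
#' @export
fit_bounds <- function(gamma = c(0, 20), eta = c(1e-4, 20),
                       theta0 = c(1e-6, pi / 2)) {
  list(gamma = gamma, eta = eta, theta0 = theta0)
}

default_starts <- function(bounds, n_starts = 8, pin_gamma = NULL) {
  etas <- c(0.3, 1, 3, 10)
  gammas <- if (is.null(pin_gamma)) c(0.5, 5) else pin_gamma
  grid <- expand.grid(eta = etas, gamma = gammas)
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  grid$theta0 <- 0.01
  grid
}

#' Fit a tip-angle trajectory to the root model
#'
#' Nonlinear least squares of an observed `theta_tip(t)` series against
#' root-model predictions, over the free parameters `gamma`, `eta` and
#' `theta0` (with `theta_g` fixed and `theta0` bounded positive).
#' A deterministic multistart (coarse grid over `eta` and `gamma`,
#' `theta0` started near zero) feeds a bounded Levenberg-Marquardt
#' optimiser; the best final sum of squares wins. Failure to converge from
#' every start yields a flagged result (`converged = FALSE`), never an
#' error.
#'
#' @param traj A trajectory tibble (see [tip_trajectory()]), >= 10 samples.
#' @param eps0 Elongation rate (1/h) used to nondimensionalise time. If
#'   `NULL`, taken from `geometry`; if that is also missing, the cohort
#'   means (`v_g = 0.13`, `L_gz = 0.6`) are used with a warning.
#' @param geometry Optional [organ_geometry()]; enables the derived
#'   `beta = eta * r / L_gz`.
#' @param theta_g Stimulus direction (default `pi/2`).
#' @param bounds Parameter box, see [fit_bounds()].
#' @param n_starts Number of multistart points (default 8).
#' @param pin_gamma Fix `gamma` at this value instead of fitting it
#'   (used by [fit_without_proprioception()]).
#' @param rtol,atol Solver tolerances for the model evaluations.
#'
#' @return An object of class `root_fit`: list with elements `gamma`, `eta`,
#'   `theta0`, `beta`, `r_squared`, `n_points`, `converged`, `covariance`,
#'   `fitted` (tibble of data and predictions), `starts`, `eps0`,
#'   `gamma_pinned`. `tidy()` gives a per-parameter tibble, `glance()` a
#'   one-row summary.
#' @export
fit_tip_trajectory <- function(traj, eps0 = NULL, geometry = NULL,
                               theta_g = pi / 2, bounds = fit_bounds(),
                               n_starts = 8, pin_gamma = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  traj <- as_tip_trajectory(traj)
  if (nrow(traj) < 10) {
    abort("Need at least 10 samples to fit.",
          class = "gravitroot_invalid_input")
  }
  if (is.null(eps0)) {
    if (!is.null(geometry)) {
      eps0 <- geometry$growth_rate
    } else {
      eps0 <- 0.13 / 0.6
      warn(sprintf(
        "No `eps0` or `geometry` supplied; falling back to cohort-mean eps0 = %.4g /h.",
        eps0))
    }
  }
  check_scalar(eps0, "eps0", 0, strict = TRUE)
  t_obs <- traj$time_h
  y_obs <- traj$theta_tip
  tau_obs <- eps0 * t_obs
  tau_max <- max(tau_obs) * (1 + 1e-9)

  predict_theta <- function(gamma, eta, theta0) {
    rhs <- function(tau, y, p) {
      list(c(y[2], -eta * sin(y[1] + y[2] + theta0 - theta_g) - gamma * y[2]))
    }
    taus <- sort(unique(c(0, tau_obs)))
    out <- try(deSolve::ode(c(K = 0, k = 0), taus, rhs, NULL,
                            method = "lsoda", rtol = rtol, atol = atol),
               silent = TRUE)
    if (inherits(out, "try-error") || attr(out, "istate")[1] < 0) {
      return(rep(NA_real_, length(tau_obs)))
    }
    Kk <- out[, "K"] + out[, "k"]
    theta0 + approx(out[, "time"], Kk, xout = tau_obs)$y
  }

  free <- if (is.null(pin_gamma)) c("gamma", "eta", "theta0") else c("eta", "theta0")
  resid_fun <- function(par) {
    p <- as.list(par)
    if (!is.null(pin_gamma)) p$gamma <- pin_gamma
    pred <- predict_theta(p$gamma, p$eta, p$theta0)
    if (anyNA(pred)) return(rep(1e6, length(y_obs)))
    y_obs - pred
  }

  starts <- default_starts(bounds, n_starts, pin_gamma)
  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- setNames(as.numeric(starts[i, free]), free)
    fit <- try(minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    ss <- fit$deviance
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && ss < best$ss)) {
      best <- list(fit = fit, ss = ss, ok = ok)
    }
  }

  ss_tot <- sum((y_obs - mean(y_obs))^2)
  degenerate <- ss_tot == 0
  if (is.null(best) || degenerate) {
    if (degenerate) warn("Constant trajectory: fit is degenerate (R^2 undefined).")
    return(new_root_fit(
      gamma = pin_gamma %||% NA_real_, eta = NA_real_, theta0 = NA_real_,
      beta = NA_real_, r_squared = NA_real_, n_points = nrow(traj),
      converged = FALSE, covariance = NULL,
      fitted = tibble(time_h = t_obs, observed = y_obs,
                      predicted = NA_real_),
      starts = starts, eps0 = eps0, gamma_pinned = !is.null(pin_gamma)
    ))
  }

  par <- coef(best$fit)
  gamma_hat <- if (is.null(pin_gamma)) par[["gamma"]] else pin_gamma
  eta_hat <- par[["eta"]]
  theta0_hat <- par[["theta0"]]
  pred <- predict_theta(gamma_hat, eta_hat, theta0_hat)
  r2 <- 1 - sum((y_obs - pred)^2) / ss_tot
  covar <- tryCatch({
    sigma2 <- best$ss / max(1, length(y_obs) - length(free))
    v <- sigma2 * solve(best$fit$hessian)
    dimnames(v) <- list(free, free)
    v
  }, error = function(e) NULL)
  beta_hat <- if (!is.null(geometry)) {
    eta_hat * geometry$radius / geometry$growth_zone
  } else {
    NA_real_
  }
  new_root_fit(
    gamma = gamma_hat, eta = eta_hat, theta0 = theta0_hat, beta = beta_hat,
    r_squared = r2, n_points = nrow(traj), converged = best$ok,
    covariance = covar,
    fitted = tibble(time_h = t_obs, observed = y_obs, predicted = pred),
    starts = starts, eps0 = eps0, gamma_pinned = !is.null(pin_gamma)
  )
}

new_root_fit <- function(...) structure(list(...), class = "root_fit")

#' Fit with proprioception disabled
#'
#' Same as [fit_tip_trajectory()] with `gamma` pinned to 0 (free parameters
#' `eta` and `theta0` only). Comparing its `R^2` with the full fit's
#' quantifies how much proprioception is needed to describe a trajectory.
#'
#' @inheritParams fit_tip_trajectory
#' @return A `root_fit` with `gamma = 0` and `gamma_pinned = TRUE`.
#' @export
fit_without_proprioception <- function(traj, eps0 = NULL, geometry = NULL,
                                       ...) {
  fit_tip_trajectory(traj, eps0 = eps0, geometry = geometry,
                     pin_gamma = 0, ...)
}

#' @export
print.root_fit <- function(x, ...) {
  cat("<root_fit>", if (x$gamma_pinned) "(gamma pinned)" else "", "\n")
  cat(sprintf("  gamma = %.4g, eta = %.4g, theta0 = %.4g rad, beta = %s\n",
              x$gamma, x$eta, x$theta0, format(x$beta, digits = 4)))
  cat(sprintf("  R^2 = %s on %d points; converged: %s\n",
              format(x$r_squared, digits = 6), x$n_points, x$converged))
  invisible(x)
}

#' @method tidy root_fit
#' @export
tidy.root_fit <- function(x, ...) {
  params <- c("gamma", "eta", "theta0", "beta")
  se <- setNames(rep(NA_real_, 4), params)
  if (!is.null(x$covariance)) {
    d <- sqrt(pmax(diag(x$covariance), 0))
    se[names(d)] <- d
  }
  tibble(
    term = params,
    estimate = c(x$gamma, x$eta, x$theta0, x$beta),
    std.error = unname(se)
  )
}

#' @method glance root_fit
#' @export
glance.root_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, nobs = x$n_points, converged = x$converged,
    gamma = x$gamma, eta = x$eta, theta0 = x$theta0, beta = x$beta,
    eps0 = x$eps0, gamma_pinned = x$gamma_pinned
  )
}

#' Gravitropic sensitivity from maximal growth-zone bending
#'
#' Model-independent estimator of `beta` from the maximal bending rate of
#' the growth zone:
#' \deqn{\beta_{bend} = \max_t \frac{d}{dt}\left(\theta_{tip} -
#'   \theta_{gz0}\right) \cdot r / v_g.}
#' The derivative of the noisy bending series is taken with a
#' Savitzky-Golay local-polynomial filter (order 2, 5-sample window by
#' default) before the maximum, since a raw finite-difference maximum is
#' upward-biased under noise. On noise-free root-model data with a
#' horizontal tilt the estimator equals `beta` in the continuum limit (the
#' maximal bending rate is `eps0 * eta` at `t = 0`).
#'
#' @param traj Trajectory tibble carrying `theta_gz0`.
#' @param geometry An [organ_geometry()] supplying `r` and `v_g`.
#' @param sg_window Savitzky-Golay window length (odd, default 5).
#' @param sg_order Polynomial order (default 2).
#' @return The `beta` estimate (dimensionless).
#' @export
beta_from_bending <- function(traj, geometry, sg_window = 5, sg_order = 2) {
  traj <- as_tip_trajectory(traj)
  if (is.null(traj[["theta_gz0"]])) {
    abort("`traj` must carry a `theta_gz0` column.",
          class = "gravitroot_invalid_input")
  }
  bend <- traj$theta_tip - traj$theta_gz0
  dt <- median(diff(traj$time_h))
  if (length(bend) < sg_window) {
    abort("Trajectory shorter than the smoothing window.",
          class = "gravitroot_invalid_input")
  }
  dbend <- signal::sgolayfilt(bend, p = sg_order, n = sg_window, m = 1,
                              ts = dt)
  max(dbend) * geometry$radius / geometry$growth_velocity
}

#' Serialise a fit to JSON
#'
#' Writes the fit report (`gamma`, `eta`, `theta0`, `beta`, `r_squared`,
#' `n_points`, `converged`, start list, eps0) as a JSON object.
#'
#' @param fit A `root_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "root_fit"))
  report <- list(
    gamma = fit$gamma, eta = fit$eta, theta0 = fit$theta0, beta = fit$beta,
    r_squared = fit$r_squared, n_points = fit$n_points,
    converged = fit$converged, eps0 = fit$eps0,
    gamma_pinned = fit$gamma_pinned,
    starts = fit$starts
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
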