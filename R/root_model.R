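#' Solve the reduced root model
#'
#' The root model couples apical gravisensing to curvature production inside
#' a finite subapical growth zone. In nondimensional variables — growth-zone
#' angle `k(tau) = L_gz * kappa_gz`, nondimensional time `tau = eps0 * t`,
#' cumulative mature-zone angle `K(tau) = integral of k` — the dynamics
#' reduce to the augmented first-order system
#'
#' \deqn{K' = k, \qquad k' = -\eta \sin(K + k + \tilde\theta_0) - \gamma k,}
#'
#' with `K(0) = k(0) = 0`. This is algebraically equivalent (by one
#' differentiation) to the second-order arcsin-form ODE for `k`, but remains
#' regular at the horizontal-tilt initial condition where the arcsin form is
#' a 0/0 expression; the stated initial slope `k'(0) = -eta * sin(theta0_tilde)`
#' is recovered automatically. The tip angle follows as
#' `theta_tip = theta0 + K + k`.
#'
#' @param eta Effective gravitropic sensitivity (> 0).
#' @param gamma Proprioceptive sensitivity (>= 0).
#' @param theta0_tilde Initial angle relative to the stimulus,
#'   `theta0 - theta_g` (radians). Horizontal gravistimulation of a root is
#'   `-pi/2`.
#' @param tau_max Nondimensional horizon (> 0). The default 10 covers about
#'   three times the typical nondimensional response duration (~3).
#' @param n_steps Number of output intervals of the dense grid.
#' @param theta_g Stimulus direction used when reporting `theta_tip`
#'   (default `pi/2`).
#' @param rtol,atol Solver tolerances (adaptive `lsoda`).
#'
#' @return An object of class `root_model_solution`: list with `params`
#'   and a tibble `solution` with columns `tau`, `k`, `K`, `theta_tip`.
#'   `tidy()` returns the tibble.
#' @examples
#' sol <- solve_root_model(eta = 1, gamma = 1.6, theta0_tilde = -pi / 2)
#' tidy(sol)
#' @export
solve_root_model <- function(eta, gamma, theta0_tilde, tau_max = 10,
                             n_steps = 1000, theta_g = pi / 2,
                             rtol = 1e-8, atol = 1e-10) {
  check_scalar(eta, "eta", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(theta0_tilde, "theta0_tilde")
  check_scalar(tau_max, "tau_max", 0, strict = TRUE)
  taus <- seq(0, tau_max, length.out = n_steps + 1)
  rhs <- function(tau, y, p) {
    list(c(y[2], -eta * sin(y[1] + y[2] + theta0_tilde) - gamma * y[2]))
  }
  out <- deSolve::ode(c(K = 0, k = 0), taus, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    abort("ODE solver failed; see diagnostics(out).",
          class = "gravitroot_numerical_error")
  }
  theta0 <- theta0_tilde + theta_g
  sol <- tibble(
    tau = out[, "time"], k = out[, "k"], K = out[, "K"],
    theta_tip = theta0 + out[, "K"] + out[, "k"]
  )
  structure(
    list(
      params = list(eta = eta, gamma = gamma, theta0_tilde = theta0_tilde,
                    theta0 = theta0, theta_g = theta_g,
                    rtol = rtol, atol = atol),
      solution = sol
    ),
    class = "root_model_solution"
  )
}

#' @method tidy root_model_solution
#' @export
tidy.root_model_solution <- function(x, ...) x$solution

#' @export
print.root_model_solution <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<root_model_solution> eta=%.4g gamma=%.4g theta0_tilde=%.4g, %d points on tau in [0, %.4g]\n",
    p$eta, p$gamma, p$theta0_tilde, nrow(x$solution), max(x$solution$tau)
  ))
  invisible(x)
}

#' Residual of the second-order arcsin-form ODE
#'
#' Cross-checks a solution of [solve_root_model()] against the equivalent
#' second-order form
#' \deqn{-\frac{k'' + \gamma k'}{\sqrt{\eta^2 - (k' + \gamma k)^2}} = k + k',}
#' evaluating `k'` and `k''` analytically from the solved system. Grid
#' points where the square-root denominator falls below `mask_tol` are
#' masked: for a horizontal tilt the form is 0/0 at `tau = 0` because
#' `k'(0) + gamma k(0) = eta` there.
#'
#' @param solution A `root_model_solution`.
#' @param mask_tol Mask points with `eta^2 - (k' + gamma k)^2 < mask_tol`.
#'
#' @return A tibble with columns `tau`, `residual`, `masked`.
#' @export
residual_eq8 <- function(solution, mask_tol = 1e-8) {
  stopifnot(inherits(solution, "root_model_solution"))
  p <- solution$params
  s <- solution$solution
  phase <- s$K + s$k + p$theta0_tilde
  kp <- -p$eta * sin(phase) - p$gamma * s$k
  kpp <- -p$eta * cos(phase) * (s$k + kp) - p$gamma * kp
  disc <- p$eta^2 - (kp + p$gamma * s$k)^2
  masked <- disc < mask_tol
  res <- rep(NA_real_, nrow(s))
  res[!masked] <- -(kpp[!masked] + p$gamma * kp[!masked]) /
    sqrt(disc[!masked]) - (s$k[!masked] + kp[!masked])
  tibble(tau = s$tau, residual = res, masked = masked)
}

#' Tip-angle trajectory from a model solution
#'
#' Maps a nondimensional solution back to laboratory time:
#' `theta_tip(t) = theta0 + K(eps0 t) + k(eps0 t)`, interpolating the dense
#' solution with cubic splines.
#'
#' @param solution A `root_model_solution`.
#' @param theta0 Initial base angle (radians). Defaults to the value implied
#'   by the solved `theta0_tilde` and `theta_g`.
#' @param eps0 Elongation rate (1/h).
#' @param times_t Output times (hours); `eps0 * times_t` must lie inside the
#'   solved range.
#'
#' @return A trajectory tibble (see [tip_trajectory()]).
#' @export
tip_angle_from_solution <- function(solution, theta0 = NULL, eps0, times_t) {
  stopifnot(inherits(solution, "root_model_solution"))
  check_scalar(eps0, "eps0", 0, strict = TRUE)
  check_finite(times_t, "times_t")
  theta0 <- theta0 %||% solution$params$theta0
  s <- solution$solution
  tau <- eps0 * times_t
  if (min(tau) < min(s$tau) - 1e-12 || max(tau) > max(s$tau) + 1e-12) {
    abort("Requested times fall outside the solved range; increase `tau_max`.",
          class = "gravitroot_invalid_input")
  }
  Kk <- spline(s$tau, s$K + s$k, xout = tau)$y
  tip_trajectory(times_t, theta0 + Kk)
}

# Interpolated k(tau) from a solution (shared by generators and fitters).
interp_k <- function(solution, tau) {
  if (length(tau) == 0) return(numeric(0))
  s <- solution$solution
  spline(s$tau, s$k, xout = tau)$y
}
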