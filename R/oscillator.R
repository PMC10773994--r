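#' Damped-oscillator reduction of the root model
#'
#' In the small-angle limit the root model linearises to
#' `k'' + (eta + gamma) k' + eta k = 0`, a damped harmonic oscillator with
#' natural angular frequency `omega0 = sqrt(eta)`, attenuation rate
#' `Gamma = eta + gamma`, quality factor `Q = sqrt(eta) / (eta + gamma)` and
#' critical proprioception `gamma_crit = 2 sqrt(eta) - eta`. The response is
#' underdamped (the tip overshoots the stimulus) exactly when
#' `gamma < gamma_crit`, i.e. `omega0^2 > Gamma^2 / 4`.
#'
#' @param eta Effective gravitropic sensitivity (> 0).
#' @param gamma Proprioceptive sensitivity (>= 0). Both arguments are
#'   vectorised.
#'
#' @return A tibble with one row per `(eta, gamma)` pair: `eta`, `gamma`,
#'   `omega0`, `Gamma`, `Q`, `gamma_crit` and `regime` (one of
#'   `"underdamped"`, `"critically_damped"`, `"overdamped"`).
#' @examples
#' oscillator_quantities(1.1, 1.6) # Q ~ 0.39, overdamped
#' @export
oscillator_quantities <- function(eta, gamma) {
  check_finite(eta, "eta")
  check_finite(gamma, "gamma")
  if (any(eta <= 0) || any(gamma < 0)) {
    abort("Require `eta > 0` and `gamma >= 0`.",
          class = "gravitroot_invalid_input")
  }
  n <- max(length(eta), length(gamma))
  eta <- rep_len(eta, n); gamma <- rep_len(gamma, n)
  gamma_crit <- 2 * sqrt(eta) - eta
  regime <- dplyr::case_when(
    abs(gamma - gamma_crit) < 1e-12 ~ "critically_damped",
    gamma < gamma_crit ~ "underdamped",
    TRUE ~ "overdamped"
  )
  tibble(
    eta = eta, gamma = gamma, omega0 = sqrt(eta), Gamma = eta + gamma,
    Q = sqrt(eta) / (eta + gamma), gamma_crit = gamma_crit, regime = regime
  )
}

#' Closed-form small-angle solution
#'
#' Exact solution of the linearised growth-zone-angle equation
#' `k'' + (eta + gamma) k' + eta k = 0` with initial data `k(0) = k0`,
#' `k'(0) = kprime0`, on all three branches (underdamped, critically damped
#' to within 1e-10 of the discriminant, overdamped).
#'
#' @inheritParams oscillator_quantities
#' @param k0,kprime0 Initial growth-zone angle and its rate.
#' @param tau_grid Nondimensional times at which to evaluate.
#'
#' @return A tibble with columns `tau` and `k`.
#' @examples
#' small_angle_solution(1, 0.5, 0, 0.05, seq(0, 10, 0.1))
#' @export
small_angle_solution <- function(eta, gamma, k0, kprime0, tau_grid) {
  check_scalar(eta, "eta", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(k0, "k0")
  check_scalar(kprime0, "kprime0")
  check_finite(tau_grid, "tau_grid")
  G <- eta + gamma
  disc <- G^2 / 4 - eta
  tau <- tau_grid
  if (abs(disc) < 1e-10) {            # critically damped (repeated root)
    k <- (k0 + (kprime0 + G / 2 * k0) * tau) * exp(-G / 2 * tau)
  } else if (disc < 0) {              # underdamped
    wd <- sqrt(-disc)
    A <- k0
    B <- (kprime0 + G / 2 * k0) / wd
    k <- exp(-G / 2 * tau) * (A * cos(wd * tau) + B * sin(wd * tau))
  } else {                            # overdamped
    rt <- sqrt(disc)
    r1 <- -G / 2 + rt
    r2 <- -G / 2 - rt
    c1 <- (kprime0 - r2 * k0) / (r1 - r2)
    c2 <- k0 - c1
    k <- c1 * exp(r1 * tau) + c2 * exp(r2 * tau)
  }
  tibble(tau = tau, k = k)
}

#' Does the nonlinear root model overshoot the stimulus?
#'
#' Integrates the root model at high accuracy with event detection on
#' `theta_tip - theta_g` and reports whether the tip crosses the stimulus
#' direction within the horizon. Used to map the overshoot boundary, which
#' the oscillator reduction predicts at `gamma = gamma_crit(eta)`.
#'
#' @inheritParams solve_root_model
#' @param tau_max Horizon (default 60; crossings near critical damping are
#'   late and exponentially small).
#' @param min_amplitude Smallest excursion beyond `theta_g` counted as an
#'   overshoot (radians). The default 1e-10 sits well above the integration
#'   noise floor (atol 1e-13) and well below the smallest genuine overshoot
#'   amplitudes arising one damping step away from the boundary (~1e-9).
#' @return `TRUE` if `theta_tip` crosses `theta_g`, else `FALSE`.
#' @export
overshoots <- function(eta, gamma, theta0_tilde = -0.05, tau_max = 60,
                       min_amplitude = 1e-10) {
  check_scalar(eta, "eta", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(theta0_tilde, "theta0_tilde")
  rhs <- function(tau, y, p) {
    list(c(y[2], -eta * sin(y[1] + y[2] + theta0_tilde) - gamma * y[2]))
  }
  rootfun <- function(tau, y, p) y[1] + y[2] + theta0_tilde
  out <- deSolve::lsodar(c(K = 0, k = 0), c(0, tau_max), rhs, NULL,
                         rtol = 1e-11, atol = 1e-13, rootfunc = rootfun)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0) return(FALSE)
  # a crossing was detected: require a real excursion beyond the stimulus,
  # not an asymptotic approach dithering at the integration noise floor
  y0 <- out[nrow(out), c("K", "k")]
  cont <- deSolve::ode(y0, seq(troot[1], troot[1] + 30, length.out = 600),
                       rhs, NULL, method = "lsoda",
                       rtol = 1e-11, atol = 1e-13)
  max(cont[, "K"] + cont[, "k"] + theta0_tilde) > min_amplitude
}
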