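#' The AC comparison model (no explicit growth)
#'
#' Apical sensing with a fixed organ length: growth is implicitly assumed to
#' drive the response but is not modelled, so the organ carries a single
#' uniform curvature state. In nondimensional variables (`k` the total angle
#' traced by the organ, `tau = eps0 t`),
#' \deqn{k' = -\eta \sin(k + \tilde\theta_0) - \gamma k, \qquad
#'   \theta_{tip} = \theta_0 + k.}
#' Without proprioception (`gamma = 0`) the tip aligns with the stimulus;
#' with `gamma > 0` it stalls at the balance point
#' `eta * sin(k* + theta0_tilde) = -gamma k*`.
#'
#' @inheritParams solve_root_model
#' @return A tibble with columns `tau`, `k`, `theta_tip`; parameters are
#'   attached as the `params` attribute.
#' @examples
#' solve_ac_model(1, 1, -pi / 2) # stalls at k* = cos(k*) ~ 0.739
#' @export
solve_ac_model <- function(eta, gamma, theta0_tilde, tau_max = 10,
                           n_steps = 1000, theta_g = pi / 2,
                           rtol = 1e-8, atol = 1e-10) {
  check_scalar(eta, "eta", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(theta0_tilde, "theta0_tilde")
  check_scalar(tau_max, "tau_max", 0, strict = TRUE)
  taus <- seq(0, tau_max, length.out = n_steps + 1)
  rhs <- function(tau, y, p) {
    list(-eta * sin(y[1] + theta0_tilde) - gamma * y[1])
  }
  out <- deSolve::ode(c(k = 0), taus, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    abort("ODE solver failed.", class = "gravitroot_numerical_error")
  }
  res <- tibble(tau = out[, "time"], k = out[, "k"],
                theta_tip = theta0_tilde + theta_g + out[, "k"])
  attr(res, "params") <- list(eta = eta, gamma = gamma,
                              theta0_tilde = theta0_tilde, theta_g = theta_g)
  res
}

#' The ACE comparison model with whole-organ exponential growth
#'
#' The growth zone is taken to span the whole organ, which therefore grows
#' exponentially, `L(tau) = L0 * exp(tau)`. Two sensing variants are
#' provided:
#'
#' * `sensing = "local"` (default): each element responds to its own
#'   inclination, as in the original angle-curvature-elongation model for
#'   aerial organs. In material coordinates `s0` (units of `L0`) the scaled
#'   curvature `q(s0, tau) = L0 * kappa` obeys
#'   `dq/dtau = -eta0 * sin(theta(s0) - theta_g) - gamma * q` with
#'   `theta(s0) = theta0 + e^tau * integral_0^{s0} q ds0'`, a stiff but
#'   fixed-dimension ODE system. This variant reproduces the phenomenology
#'   expected of exponential growth: the tip overshoots the stimulus and,
#'   for moderate proprioception, keeps oscillating on the solved horizon
#'   (passive orientation drift is amplified by the exponentially growing
#'   lever arm).
#' * `sensing = "apical"`: the whole organ responds to the tip angle, so the
#'   curvature stays uniform and the dynamics collapse to the scalar ODE
#'   `qhat' = -eta(tau) * sin(e^tau * qhat + theta0_tilde) - gamma * qhat`
#'   with `theta_tip = theta0 + e^tau * qhat`. `eta_definition` selects
#'   whether the gravitropic gain is fixed at its initial value
#'   (`"initial"`, `eta(tau) = eta0`) or scales with the instantaneous
#'   length (`"instantaneous"`, `eta(tau) = eta0 * e^tau`).
#'
#' @param eta0 Effective gravitropic sensitivity defined with the initial
#'   length, `beta * L0 / r` (> 0).
#' @inheritParams solve_root_model
#' @param sensing `"local"` or `"apical"` (see Details).
#' @param eta_definition For apical sensing only: `"initial"` or
#'   `"instantaneous"`.
#' @param n_material Number of material grid points for local sensing.
#'
#' @return A tibble with columns `tau`, `theta_tip` (and `qhat` for apical
#'   sensing); parameters attached as the `params` attribute.
#' @examples
#' traj <- solve_ace_exponential(1, 1, -pi / 2, tau_max = 6)
#' @export
solve_ace_exponential <- function(eta0, gamma, theta0_tilde, tau_max = 10,
                                  n_steps = 500,
                                  sensing = c("local", "apical"),
                                  eta_definition = c("initial", "instantaneous"),
                                  n_material = 200, theta_g = pi / 2,
                                  rtol = 1e-8, atol = 1e-10) {
  check_scalar(eta0, "eta0", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0)
  check_scalar(theta0_tilde, "theta0_tilde")
  check_scalar(tau_max, "tau_max", 0, strict = TRUE)
  sensing <- match.arg(sensing)
  eta_definition <- match.arg(eta_definition)
  theta0 <- theta0_tilde + theta_g
  taus <- seq(0, tau_max, length.out = n_steps + 1)
  if (sensing == "apical") {
    rhs <- function(tau, y, p) {
      eta_t <- if (eta_definition == "instantaneous") eta0 * exp(tau) else eta0
      list(-eta_t * sin(exp(tau) * y[1] + theta0_tilde) - gamma * y[1])
    }
    out <- deSolve::ode(c(qhat = 0), taus, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort("ODE solver failed.", class = "gravitroot_numerical_error")
    }
    res <- tibble(tau = out[, "time"], qhat = out[, "qhat"],
                  theta_tip = theta0 + exp(out[, "time"]) * out[, "qhat"])
  } else {
    n <- n_material
    if (n < 50) {
      abort("`n_material` must be at least 50.",
            class = "gravitroot_invalid_input")
    }
    s0 <- seq(0, 1, length.out = n)
    ds0 <- s0[2] - s0[1]
    rhs <- function(tau, q, p) {
      theta <- theta0 +
        exp(tau) * cumsum(c(0, (head(q, -1) + tail(q, -1)) / 2 * ds0))
      list(-eta0 * sin(theta - theta_g) - gamma * q)
    }
    out <- deSolve::ode(rep(0, n), taus, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort("ODE solver failed.", class = "gravitroot_numerical_error")
    }
    q <- out[, -1, drop = FALSE]
    tip <- theta0 + exp(taus) *
      (rowSums(q) - 0.5 * q[, 1] - 0.5 * q[, n]) * ds0
    res <- tibble(tau = taus, theta_tip = tip)
  }
  attr(res, "params") <- list(eta0 = eta0, gamma = gamma,
                              theta0_tilde = theta0_tilde, theta_g = theta_g,
                              sensing = sensing,
                              eta_definition = eta_definition)
  res
}
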