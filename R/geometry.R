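#' Physical geometry of a growing root
#'
#' Bundles the per-root physical parameters of the model: the organ radius
#' `r`, the length of the subapical growth zone `L_gz`, the initial organ
#' length `L_0`, the tip growth velocity `v_g` and the elongation rate
#' `eps0`. Units are millimetres and hours. The elongation rate and tip
#' velocity are linked by `eps0 = v_g / L_gz` (uniform elongation across the
#' growth zone); supplying both with a relative disagreement above 1e-9 is an
#' error. The model derivation assumes `L_0 = L_gz`; a larger `L_0` only adds
#' a pre-existing straight mature zone.
#'
#' Defaults are the cohort means measured for *Arabidopsis thaliana* roots:
#' `r = 0.065` mm, `L_gz = 0.6` mm, `v_g = 0.13` mm/h.
#'
#' @param radius Organ radius in mm (> 0).
#' @param growth_zone Growth-zone length `L_gz` in mm (> 0).
#' @param initial_length Initial organ length `L_0` in mm (>= `growth_zone`).
#' @param growth_velocity Tip growth velocity `v_g` in mm/h (> 0).
#' @param growth_rate Elongation rate `eps0` in 1/h. Defaults to
#'   `growth_velocity / growth_zone`.
#'
#' @return An object of class `organ_geometry`: a named list with elements
#'   `radius`, `growth_zone`, `initial_length`, `growth_velocity`,
#'   `growth_rate`.
#' @examples
#' geom <- organ_geometry()
#' geom$growth_rate # ~0.217 / h
#' @export
organ_geometry <- function(radius = 0.065, growth_zone = 0.6,
                           initial_length = growth_zone,
                           growth_velocity = 0.13,
                           growth_rate = NULL) {
  check_scalar(radius, "radius", 0, strict = TRUE)
  check_scalar(growth_zone, "growth_zone", 0, strict = TRUE)
  check_scalar(initial_length, "initial_length", 0, strict = TRUE)
  check_scalar(growth_velocity, "growth_velocity", 0, strict = TRUE)
  if (initial_length < growth_zone * (1 - 1e-12)) {
    abort("`initial_length` must be >= `growth_zone`.",
          class = "gravitroot_invalid_input")
  }
  implied <- growth_velocity / growth_zone
  if (is.null(growth_rate)) {
    growth_rate <- implied
  } else {
    check_scalar(growth_rate, "growth_rate", 0, strict = TRUE)
    if (abs(growth_rate - implied) > 1e-9 * max(abs(implied), 1e-300)) {
      abort(
        "`growth_rate` is inconsistent with `growth_velocity / growth_zone`.",
        class = "gravitroot_invalid_input"
      )
    }
  }
  structure(
    list(radius = radius, growth_zone = growth_zone,
         initial_length = initial_length,
         growth_velocity = growth_velocity, growth_rate = growth_rate),
    class = "organ_geometry"
  )
}

#' @export
print.organ_geometry <- function(x, ...) {
  cat("<organ_geometry>\n")
  cat(sprintf("  radius          %.4g mm\n", x$radius))
  cat(sprintf("  growth zone     %.4g mm\n", x$growth_zone))
  cat(sprintf("  initial length  %.4g mm\n", x$initial_length))
  cat(sprintf("  tip velocity    %.4g mm/h\n", x$growth_velocity))
  cat(sprintf("  growth rate     %.4g /h\n", x$growth_rate))
  invisible(x)
}

#' Tropic sensitivities of the root model
#'
#' Bundles the dimensionless model parameters: the gravitropic sensitivity
#' `beta` (gain converting sensed inclination into curvature production), the
#' proprioceptive sensitivity `gamma` (gain of the curvature-straightening
#' response), the effective gravitropic sensitivity `eta = beta * L_gz / r`
#' (beta amplified by the slenderness of the growth zone), the initial base
#' angle `theta0` and the stimulus direction `theta_g` (both radians,
#' measured from the horizontal; gravity for a root growing downwards in the
#' figure convention used here is `theta_g = pi/2`).
#'
#' Exactly one of `beta` or `eta` must be resolvable: pass `eta` directly,
#' or pass `beta` together with `geometry`. If both `beta` and `eta` are
#' given they must agree through the geometry to a relative 1e-9.
#'
#' @param gamma Proprioceptive sensitivity (>= 0).
#' @param beta Gravitropic sensitivity (> 0), requires `geometry`.
#' @param eta Effective gravitropic sensitivity (> 0).
#' @param theta0 Initial angle at the organ base, radians.
#' @param theta_g Stimulus direction, radians (default `pi/2`).
#' @param geometry Optional [organ_geometry()] used to convert between
#'   `beta` and `eta`.
#'
#' @return An object of class `sensitivities`: named list with `beta` (may be
#'   `NA` when no geometry is known), `gamma`, `eta`, `theta0`, `theta_g` and
#'   `theta0_tilde = theta0 - theta_g`.
#' @examples
#' sensitivities(gamma = 1.6, beta = 0.12, geometry = organ_geometry())
#' sensitivities(gamma = 1.6, eta = 1.1)
#' @export
sensitivities <- function(gamma, beta = NULL, eta = NULL, theta0 = 0,
                          theta_g = pi / 2, geometry = NULL) {
  check_scalar(gamma, "gamma", 0)
  check_scalar(theta0, "theta0")
  check_scalar(theta_g, "theta_g")
  if (is.null(eta) && is.null(beta)) {
    abort("Supply `eta`, or `beta` together with `geometry`.",
          class = "gravitroot_invalid_input")
  }
  if (!is.null(beta)) {
    check_scalar(beta, "beta", 0, strict = TRUE)
    if (is.null(geometry)) {
      abort("`beta` needs `geometry` to resolve `eta = beta * L_gz / r`.",
            class = "gravitroot_invalid_input")
    }
    eta_implied <- beta * geometry$growth_zone / geometry$radius
    if (is.null(eta)) {
      eta <- eta_implied
    } else if (abs(eta - eta_implied) > 1e-9 * abs(eta_implied)) {
      abort("`eta` is inconsistent with `beta * L_gz / r`.",
            class = "gravitroot_invalid_input")
    }
  }
  check_scalar(eta, "eta", 0, strict = TRUE)
  if (is.null(beta)) {
    beta <- if (!is.null(geometry)) {
      eta * geometry$radius / geometry$growth_zone
    } else {
      NA_real_
    }
  }
  structure(
    list(beta = beta, gamma = gamma, eta = eta, theta0 = theta0,
         theta_g = theta_g, theta0_tilde = theta0 - theta_g),
    class = "sensitivities"
  )
}

#' @export
print.sensitivities <- function(x, ...) {
  cat("<sensitivities>\n")
  cat(sprintf("  beta   %s\n", format(x$beta, digits = 4)))
  cat(sprintf("  gamma  %.4g\n", x$gamma))
  cat(sprintf("  eta    %.4g\n", x$eta))
  cat(sprintf("  theta0 %.4g rad  (theta_g = %.4g rad)\n", x$theta0, x$theta_g))
  invisible(x)
}

#' Map between physical and nondimensional model variables
#'
#' The reduced model lives in nondimensional variables: the effective
#' sensitivity `eta = beta * L_gz / r` and the nondimensional time
#' `tau = eps0 * t`, the organ growth expressed in units of the growth-zone
#' length. `nondimensionalize()` maps `(beta, t)` to `(eta, tau)`;
#' `dimensionalize()` is its exact inverse.
#'
#' @param geometry An [organ_geometry()].
#' @param beta,eta Gravitropic sensitivity in the respective system (optional).
#' @param t,tau Time in hours / nondimensional time (optional, vectorised).
#'
#' @return A named list with the converted quantities (`eta` and/or `tau`,
#'   respectively `beta` and/or `t`); components not requested are `NULL`.
#' @examples
#' nondimensionalize(organ_geometry(), beta = 0.12, t = 24)
#' @export
nondimensionalize <- function(geometry, beta = NULL, t = NULL) {
  if (geometry$radius <= 0) {
    abort("zero or negative radius", class = "gravitroot_invalid_input")
  }
  out <- list(eta = NULL, tau = NULL)
  if (!is.null(beta)) {
    check_finite(beta, "beta")
    out$eta <- beta * geometry$growth_zone / geometry$radius
  }
  if (!is.null(t)) {
    check_finite(t, "t")
    out$tau <- geometry$growth_rate * t
  }
  out
}

#' @rdname nondimensionalize
#' @export
dimensionalize <- function(geometry, eta = NULL, tau = NULL) {
  out <- list(beta = NULL, t = NULL)
  if (!is.null(eta)) {
    check_finite(eta, "eta")
    out$beta <- eta * geometry$radius / geometry$growth_zone
  }
  if (!is.null(tau)) {
    check_finite(tau, "tau")
    out$t <- tau / geometry$growth_rate
  }
  out
}
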