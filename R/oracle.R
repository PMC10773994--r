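#' Axial growth-rate profile of the growth zone
#'
#' Describes how the elongation rate is distributed over the growth zone.
#' `eps_fun(x, geometry)` returns the elongation-rate density (1/h) at
#' distance `x` from the basal end of the growth zone, `x` in `[0, L_gz]`;
#' its integral over the growth zone must equal the tip velocity `v_g`
#' (checked to relative 1e-9 at construction against the supplied geometry).
#'
#' * `"uniform"`: `eps(x) = eps0 = v_g / L_gz` (the root-model assumption);
#' * `"triangular"`: `eps(x) = 2 eps0 (1 - |2x/L_gz - 1|)`, peaking mid-zone
#'   with the same integral, used for robustness checks;
#' * `"custom"`: supply `eps_fun` yourself.
#'
#' @param shape `"uniform"`, `"triangular"` or `"custom"`.
#' @param eps_fun For `shape = "custom"`: function of `(x, geometry)`.
#' @param geometry Geometry used to validate the integral constraint.
#'
#' @return An object of class `growth_profile`: list with `shape`, `eps_fun`
#'   and `vel_fun(x, geometry)`, the within-zone velocity
#'   `integral_0^x eps`.
#' @export
growth_profile <- function(shape = c("uniform", "triangular", "custom"),
                           eps_fun = NULL, geometry = organ_geometry()) {
  shape <- match.arg(shape)
  if (shape == "uniform") {
    eps_fun <- function(x, geometry) {
      rep(geometry$growth_rate, length(x))
    }
    vel_fun <- function(x, geometry) geometry$growth_rate * x
  } else if (shape == "triangular") {
    eps_fun <- function(x, geometry) {
      u <- x / geometry$growth_zone
      2 * geometry$growth_rate * (1 - abs(2 * u - 1))
    }
    vel_fun <- function(x, geometry) {
      Lgz <- geometry$growth_zone
      u <- pmin(pmax(x / Lgz, 0), 1)
      # closed-form integral of the triangle
      v <- ifelse(u <= 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)
      geometry$growth_velocity * v
    }
  } else {
    if (is.null(eps_fun)) {
      abort("`shape = \"custom\"` requires `eps_fun`.",
            class = "gravitroot_invalid_input")
    }
    vel_fun <- function(x, geometry) {
      vapply(x, function(xi) {
        stats::integrate(function(u) eps_fun(u, geometry), 0, xi,
                         rel.tol = 1e-10)$value
      }, numeric(1))
    }
  }
  total <- vel_fun(geometry$growth_zone, geometry)
  if (abs(total - geometry$growth_velocity) >
      1e-9 * abs(geometry$growth_velocity)) {
    abort("Growth profile does not integrate to the tip velocity `v_g`.",
          class = "gravitroot_invalid_input")
  }
  structure(list(shape = shape, eps_fun = eps_fun, vel_fun = vel_fun),
            class = "growth_profile")
}

#' Lagrangian material-point solver for the growth transport equation
#'
#' Direct simulation of the dimensional model
#' \deqn{\frac{r}{\dot\varepsilon(s,t)} \frac{D\kappa}{Dt} =
#'   -\beta \sin(\theta_{sense} - \theta_g) - \gamma r \kappa,}
#' following material points as they advect with the growth velocity
#' `v(s,t) = integral_0^s eps(u,t) du`. Curvature production happens only
#' where the elongation rate is nonzero, so points leaving the growth zone
#' freeze their curvature automatically; the base is clamped at
#' `theta(0, t) = theta0`. With `sensing = "apical"` every growth-zone
#' element responds to the tip angle; `"local"` uses the element's own
#' inclination. Arbitrary growth-rate profiles are supported through
#' [growth_profile()].
#'
#' This solver is deliberately independent of [solve_root_model()] — a
#' fixed-step second-order (midpoint) scheme on an adaptive material grid —
#' and serves as the reference for validating the reduced ODE.
#'
#' @param geometry An [organ_geometry()].
#' @param sens A [sensitivities()] (must carry `beta`, i.e. geometry-aware).
#' @param profile A [growth_profile()].
#' @param sensing `"apical"` (default) or `"local"`.
#' @param t_max Simulated duration (hours).
#' @param n_material_points Initial number of material points (>= 50).
#' @param dt Time step (hours). Default `min(0.25 / (eta + gamma + 1), 0.025) / eps0`.
#' @param out_times Times at which to record the tip angle (default 200
#'   evenly spaced).
#' @param kymo_ds If not `NULL`, also record curvature interpolated on a
#'   fixed arc-length grid of this spacing (mm), as a long kymograph tibble.
#'
#' @return A list with `trajectory` (tibble `time_h`, `theta_tip`,
#'   `theta_gz0`, `length_mm`) and `kymograph` (long tibble or `NULL`).
#' @examples
#' sens <- sensitivities(gamma = 2, eta = 1, theta0 = 0, geometry = organ_geometry())
#' sim <- lagrangian_oracle(organ_geometry(), sens, t_max = 10,
#'                          n_material_points = 100)
#' @export
lagrangian_oracle <- function(geometry, sens,
                              profile = growth_profile("uniform", geometry = geometry),
                              sensing = c("apical", "local"),
                              t_max = 24, n_material_points = 400,
                              dt = NULL, out_times = NULL, kymo_ds = NULL) {
  sensing <- match.arg(sensing)
  if (n_material_points < 50) {
    abort("`n_material_points` must be >= 50.",
          class = "gravitroot_invalid_input")
  }
  if (!is.finite(sens$beta)) {
    abort("`sens` must carry `beta` (construct it with a geometry).",
          class = "gravitroot_invalid_input")
  }
  eps0 <- geometry$growth_rate
  Lgz <- geometry$growth_zone
  r <- geometry$radius
  beta <- sens$beta
  gamma <- sens$gamma
  theta0 <- sens$theta0
  theta_g <- sens$theta_g
  eta <- sens$eta
  if (is.null(dt)) dt <- min(0.25 / (eta + gamma + 1), 0.025) / eps0
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(t_max, "t_max", 0, strict = TRUE)
  if (is.null(out_times)) out_times <- seq(0, t_max, length.out = 200)

  s <- seq(0, geometry$initial_length, length.out = n_material_points)
  kap <- numeric(n_material_points)
  ds0 <- s[2] - s[1]

  theta_of <- function(s, kap) {
    theta0 + cumsum(c(0, diff(s) * (head(kap, -1) + tail(kap, -1)) / 2))
  }
  deriv <- function(s, kap) {
    L <- s[length(s)]
    x <- pmin(pmax(s - (L - Lgz), 0), Lgz)    # position within the growth zone
    eps_local <- ifelse(s > L - Lgz, profile$eps_fun(x, geometry), 0)
    v <- profile$vel_fun(x, geometry)
    th <- theta_of(s, kap)
    sense <- if (sensing == "apical") th[length(th)] else th
    dkap <- (eps_local / r) * (-beta * sin(sense - theta_g) - gamma * r * kap)
    list(ds = v, dkap = dkap)
  }

  out_times <- sort(unique(c(0, out_times)))
  rec_t <- numeric(0); rec_tip <- numeric(0); rec_gz0 <- numeric(0)
  rec_L <- numeric(0)
  kymo <- if (!is.null(kymo_ds)) vector("list", length(out_times)) else NULL

  record <- function(i_out, s, kap) {
    th <- theta_of(s, kap)
    L <- s[length(s)]
    rec_t <<- c(rec_t, out_times[i_out])
    rec_tip <<- c(rec_tip, th[length(th)])
    rec_gz0 <<- c(rec_gz0, approx(s, th, xout = max(L - Lgz, 0))$y)
    rec_L <<- c(rec_L, L)
    if (!is.null(kymo)) {
      sg <- seq(0, L, by = kymo_ds)
      kymo[[i_out]] <<- tibble(
        time_h = out_times[i_out], s_mm = sg,
        kappa = approx(s, kap, xout = sg, rule = 2)$y,
        length_mm = L
      )
    }
  }

  record(1, s, kap)
  for (i_out in seq_along(out_times)[-1]) {
    # subdivide each output interval so steps land exactly on output times
    seg <- out_times[i_out] - out_times[i_out - 1]
    m <- max(1, ceiling(seg / dt))
    h <- seg / m
    for (step in seq_len(m)) {
      # midpoint (RK2) update of positions and curvatures
      d1 <- deriv(s, kap)
      s_half <- s + 0.5 * h * d1$ds
      kap_half <- kap + 0.5 * h * d1$dkap
      d2 <- deriv(s_half, kap_half)
      s <- s + h * d2$ds
      kap <- kap + h * d2$dkap
      if (any(!is.finite(kap))) {
        abort("Material-point update became unstable; reduce `dt`.",
              class = "gravitroot_numerical_error")
      }
      # refine stretched intervals so the growth zone stays resolved
      gap <- diff(s)
      wide <- which(gap > 1.5 * ds0)
      if (length(wide) > 0) {
        new_s <- (s[wide] + s[wide + 1]) / 2
        new_k <- (kap[wide] + kap[wide + 1]) / 2
        idx <- order(c(seq_along(s), wide + 0.5))
        s <- c(s, new_s)[idx]
        kap <- c(kap, new_k)[idx]
      }
    }
    record(i_out, s, kap)
  }

  list(
    trajectory = tip_trajectory(rec_t, rec_tip, theta_gz0 = rec_gz0,
                                length_mm = rec_L),
    kymograph = if (!is.null(kymo)) dplyr::bind_rows(kymo) else NULL
  )
}
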