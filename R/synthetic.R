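#' Simulate a sampled tip-angle trajectory with known ground truth
#'
#' Runs the root model forward and samples it on the experimental imaging
#' grid, adding independent Gaussian angle noise. The defaults emulate the
#' horizontal-gravistimulation protocol: pictures every 10 minutes
#' (`dt = 1/6` h) for 24 h, giving 145 samples. When `include_gz0` is set,
#' the angle at the growth-zone base is reported as
#' `theta_gz0 = theta_tip - k` (the growth zone traces the angle `k`), with
#' its own independent noise.
#'
#' @param geometry An [organ_geometry()].
#' @param sens A [sensitivities()].
#' @param noise_sigma Standard deviation of the additive angle noise
#'   (radians), default 0.02 (~1.1 degrees).
#' @param dt Sampling interval (hours), default 1/6.
#' @param duration Record length (hours), default 24.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param include_gz0,include_length Include the `theta_gz0` / `length_mm`
#'   columns.
#' @param length_noise_sigma Noise on the length series (mm), default 0.
#'
#' @return A list with `trajectory` (tibble) and `truth`, a one-row tibble
#'   recording every generating parameter.
#' @examples
#' sim <- generate_trajectory(organ_geometry(),
#'   sensitivities(gamma = 1.6, eta = 1.1), seed = 1)
#' @export
generate_trajectory <- function(geometry, sens, noise_sigma = 0.02,
                                dt = 1 / 6, duration = 24, seed = NULL,
                                include_gz0 = TRUE, include_length = TRUE,
                                length_noise_sigma = 0) {
  check_scalar(noise_sigma, "noise_sigma", 0)
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(duration, "duration", 0, strict = TRUE)
  eps0 <- geometry$growth_rate
  times <- seq(0, duration, by = dt)
  sol <- solve_root_model(sens$eta, sens$gamma, sens$theta0_tilde,
                          tau_max = eps0 * duration * (1 + 1e-9) + 1e-9,
                          theta_g = sens$theta_g)
  clean <- tip_angle_from_solution(sol, theta0 = sens$theta0, eps0 = eps0,
                                   times_t = times)
  k <- interp_k(sol, eps0 * times)
  L <- geometry$initial_length + geometry$growth_zone * eps0 * times
  with_seed(seed, {
    theta_tip <- clean$theta_tip + rnorm(length(times), 0, noise_sigma)
    theta_gz0 <- if (include_gz0) {
      clean$theta_tip - k + rnorm(length(times), 0, noise_sigma)
    } else {
      NULL
    }
    length_mm <- if (include_length) {
      L + rnorm(length(times), 0, length_noise_sigma)
    } else {
      NULL
    }
    list(
      trajectory = tip_trajectory(times, theta_tip, theta_gz0 = theta_gz0,
                                  length_mm = length_mm),
      truth = tibble(
        eta = sens$eta, gamma = sens$gamma, beta = sens$beta,
        theta0 = sens$theta0, theta_g = sens$theta_g,
        radius = geometry$radius, growth_zone = geometry$growth_zone,
        initial_length = geometry$initial_length,
        growth_velocity = geometry$growth_velocity, eps0 = eps0,
        noise_sigma = noise_sigma, dt = dt, duration = duration,
        seed = seed %||% NA_real_
      )
    )
  })
}

#' Simulate a curvature kymograph with known ground truth
#'
#' Wraps [solve_root_model()] and [reconstruct_shape_history()]; cells
#' beyond the organ (`s > L(t)`) are omitted (masked). Optional
#' multiplicative noise emulates curvature measurement error.
#'
#' @inheritParams generate_trajectory
#' @param t_grid Output times (hours); default 25 times over `duration`.
#' @param ds Arc-length resolution (mm).
#' @param noise_cv Coefficient of variation of multiplicative curvature
#'   noise (default 0, noise-free).
#' @return A list with `kymograph` (long tibble), `centerlines` and `truth`.
#' @export
generate_kymograph <- function(geometry, sens, t_grid = NULL, ds = 0.01,
                               duration = 24, noise_cv = 0, seed = NULL) {
  check_scalar(noise_cv, "noise_cv", 0)
  eps0 <- geometry$growth_rate
  if (is.null(t_grid)) t_grid <- seq(0, duration, length.out = 25)
  sol <- solve_root_model(sens$eta, sens$gamma, sens$theta0_tilde,
                          tau_max = eps0 * max(t_grid) * (1 + 1e-9) + 1e-9,
                          theta_g = sens$theta_g)
  sh <- reconstruct_shape_history(sol, geometry, t_grid = t_grid, ds = ds)
  kymo <- sh$kymograph
  if (noise_cv > 0) {
    kymo <- with_seed(seed, {
      dplyr::mutate(kymo,
                    kappa = .data$kappa * (1 + rnorm(dplyr::n(), 0, noise_cv)))
    })
  }
  list(kymograph = kymo, centerlines = sh$centerlines,
       truth = tibble(eta = sens$eta, gamma = sens$gamma,
                      theta0 = sens$theta0, growth_zone = geometry$growth_zone,
                      eps0 = eps0, ds = ds, noise_cv = noise_cv,
                      seed = seed %||% NA_real_))
}

#' Specification of a synthetic root cohort
#'
#' Describes the population from which per-root parameters are drawn:
#' independent truncated normals (truncated to positive values) with the
#' cohort means and spreads measured for *Arabidopsis* roots, and a
#' half-normal initial angle `theta0` emulating small placement scatter
#' around the horizontal. The default `n_roots = 114` matches the size of
#' the emulated experiment.
#'
#' @param n_roots Number of roots.
#' @param means,sds Named numeric vectors with entries `beta`, `gamma`, `r`
#'   (mm), `Lgz` (mm), `vg` (mm/h): population means and standard
#'   deviations.
#' @param theta0_scale Scale of the half-normal initial angle (radians).
#' @param noise_sigma,dt,duration Passed to [generate_trajectory()].
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_roots = 114,
                        means = c(beta = 0.12, gamma = 1.6, r = 0.065,
                                  Lgz = 0.6, vg = 0.13),
                        sds = c(beta = 0.06, gamma = 1.0, r = 0.011,
                                Lgz = 0.14, vg = 0.04),
                        theta0_scale = 0.05, noise_sigma = 0.02,
                        dt = 1 / 6, duration = 24, seed = 1) {
  check_scalar(n_roots, "n_roots", 0)
  need <- c("beta", "gamma", "r", "Lgz", "vg")
  if (!all(need %in% names(means)) || !all(need %in% names(sds))) {
    abort("`means` and `sds` need entries beta, gamma, r, Lgz, vg.",
          class = "gravitroot_invalid_input")
  }
  if (any(means[setdiff(need, "gamma")] <= 0) || means[["gamma"]] < 0) {
    abort("All parameter means must be positive.",
          class = "gravitroot_invalid_input")
  }
  if (duration / dt < 10) {
    abort("Need at least 10 samples per trajectory.",
          class = "gravitroot_invalid_input")
  }
  structure(
    list(n_roots = as.integer(n_roots), means = means[need], sds = sds[need],
         theta0_scale = theta0_scale, noise_sigma = noise_sigma, dt = dt,
         duration = duration, seed = seed),
    class = "cohort_spec"
  )
}

# Truncated-normal sampler (lower truncation), inverse-CDF so the number of
# uniforms consumed is deterministic.
rtruncnorm_lower <- function(n, mean, sd, lower = 1e-6) {
  p_lo <- stats::pnorm((lower - mean) / sd)
  qnorm(runif(n, p_lo, 1)) * sd + mean
}

#' Generate a synthetic cohort of gravistimulated roots
#'
#' Draws per-root parameters from the population in a [cohort_spec()],
#' simulates one noisy trajectory per root, and returns both the
#' trajectories and a machine-readable truth table. With `dir` set, each
#' trajectory is written as `root_###.csv` beside a `truth.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory (created if needed).
#' @return A tibble with one row per root: the generating parameters
#'   (`root`, `beta`, `gamma`, `eta`, `theta0`, `radius`, `growth_zone`,
#'   `growth_velocity`, `eps0`) and a list-column `trajectory`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_roots
  if (n == 0) {
    out <- tibble(
      root = integer(0), beta = numeric(0), gamma = numeric(0),
      eta = numeric(0), theta0 = numeric(0), radius = numeric(0),
      growth_zone = numeric(0), growth_velocity = numeric(0),
      eps0 = numeric(0), trajectory = list()
    )
    if (!is.null(dir)) write_truth_table(out, dir)
    return(out)
  }
  draws <- with_seed(spec$seed, {
    m <- spec$means; s <- spec$sds
    tibble(
      root = seq_len(n),
      beta = rtruncnorm_lower(n, m[["beta"]], s[["beta"]]),
      gamma = rtruncnorm_lower(n, m[["gamma"]], s[["gamma"]], lower = 0),
      radius = rtruncnorm_lower(n, m[["r"]], s[["r"]]),
      growth_zone = rtruncnorm_lower(n, m[["Lgz"]], s[["Lgz"]]),
      growth_velocity = rtruncnorm_lower(n, m[["vg"]], s[["vg"]]),
      theta0 = abs(rnorm(n, 0, spec$theta0_scale)),
      traj_seed = sample.int(.Machine$integer.max, n)
    )
  })
  draws$eta <- draws$beta * draws$growth_zone / draws$radius
  draws$eps0 <- draws$growth_velocity / draws$growth_zone
  draws$trajectory <- purrr::pmap(
    draws[, c("beta", "gamma", "theta0", "radius", "growth_zone",
              "growth_velocity", "traj_seed")],
    function(beta, gamma, theta0, radius, growth_zone, growth_velocity,
             traj_seed) {
      geom <- organ_geometry(radius = radius, growth_zone = growth_zone,
                             growth_velocity = growth_velocity)
      sens <- sensitivities(gamma = gamma, beta = beta, theta0 = theta0,
                            geometry = geom)
      generate_trajectory(geom, sens, noise_sigma = spec$noise_sigma,
                          dt = spec$dt, duration = spec$duration,
                          seed = traj_seed)$trajectory
    }
  )
  out <- draws[, c("root", "beta", "gamma", "eta", "theta0", "radius",
                   "growth_zone", "growth_velocity", "eps0", "traj_seed",
                   "trajectory")]
  if (!is.null(dir)) write_truth_table(out, dir)
  out
}

write_truth_table <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- dplyr::select(cohort, -dplyr::any_of("trajectory"))
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  purrr::walk2(cohort$trajectory, cohort$root, function(traj, id) {
    write_trajectory(traj, file.path(dir, sprintf("root_%03d.csv", id)))
  })
  invisible(dir)
}
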