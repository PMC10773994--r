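#' Reconstruct the space-time shape history of a solved root
#'
#' Converts a nondimensional solution into physical curvature fields and
#' centerlines. With apical sensing the growth zone carries a spatially
#' uniform curvature `kappa_gz(t) = k(eps0 t) / L_gz`; material leaving the
#' growth zone freezes its curvature, so the mature zone carries
#' `kappa_mz(s) = kappa_gz(t')` where `s = L_mz(t')` is the arc length at
#' which that element exited. The organ length grows linearly,
#' `L(t) = L0 + L_gz * eps0 * t`, the curvature field is continuous (but not
#' smooth) at the growth-zone boundary, and any pre-existing mature zone
#' (`L0 > L_gz`) is straight.
#'
#' @param solution A `root_model_solution`.
#' @param geometry An [organ_geometry()].
#' @param t_grid Output times (hours). Default: 25 times spanning the solved
#'   horizon.
#' @param ds Arc-length resolution of the reconstruction grid (mm),
#'   default 0.01 (10 microns).
#'
#' @return A list of class `shape_history` with elements
#'   `kymograph` — long tibble (`time_h`, `s_mm`, `kappa`, `length_mm`),
#'   cells with `s > L(t)` omitted (masked) — and `centerlines`, a tibble
#'   with columns `time_h` and a list-column `centerline` of centerline
#'   tibbles.
#' @examples
#' sol <- solve_root_model(1.1, 1.6, -pi / 2, tau_max = 5)
#' sh <- reconstruct_shape_history(sol, organ_geometry())
#' @export
reconstruct_shape_history <- function(solution, geometry, t_grid = NULL,
                                      ds = 0.01) {
  stopifnot(inherits(solution, "root_model_solution"))
  if (!inherits(geometry, "organ_geometry")) {
    abort("`geometry` must be an `organ_geometry`.",
          class = "gravitroot_invalid_input")
  }
  check_scalar(ds, "ds", 0, strict = TRUE)
  eps0 <- geometry$growth_rate
  Lgz <- geometry$growth_zone
  L0 <- geometry$initial_length
  tau_max <- max(solution$solution$tau)
  if (is.null(t_grid)) t_grid <- seq(0, tau_max / eps0, length.out = 25)
  check_finite(t_grid, "t_grid")
  if (max(t_grid) * eps0 > tau_max + 1e-9) {
    abort("`t_grid` extends past the solved horizon.",
          class = "gravitroot_invalid_input")
  }
  theta0 <- solution$params$theta0
  kappa_profile <- function(t) {
    L <- L0 + Lgz * eps0 * t
    s <- seq(0, L, by = ds)
    if (s[length(s)] < L - 1e-12) s <- c(s, L)
    Lmz_pre <- L0 - Lgz           # straight pre-existing mature zone
    Lmz <- L - Lgz
    kappa <- numeric(length(s))
    grown <- s > Lmz_pre & s <= Lmz
    # element at arc s exited the growth zone at time t' with s = Lmz(t')
    tau_exit <- (s[grown] - Lmz_pre) / Lgz
    kappa[grown] <- interp_k(solution, tau_exit) / Lgz
    gz <- s > Lmz
    kappa[gz] <- interp_k(solution, eps0 * t) / Lgz
    tibble(s_mm = s, kappa = kappa, length_mm = L)
  }
  kymo <- purrr::map(t_grid, function(t) {
    dplyr::mutate(kappa_profile(t), time_h = t)
  })
  kymo <- dplyr::bind_rows(kymo)[, c("time_h", "s_mm", "kappa", "length_mm")]
  centerlines <- tibble(
    time_h = t_grid,
    centerline = purrr::map(t_grid, function(t) {
      prof <- kappa_profile(t)
      theta <- theta0 + pracma::cumtrapz(prof$s_mm, prof$kappa)[, 1]
      integrate_shape(theta, prof$s_mm)
    })
  )
  structure(list(kymograph = kymo, centerlines = centerlines),
            class = "shape_history")
}

#' @export
print.shape_history <- function(x, ...) {
  cat(sprintf("<shape_history> %d times, %d kymograph cells\n",
              nrow(x$centerlines), nrow(x$kymograph)))
  invisible(x)
}

# Validate a long-format kymograph tibble.
check_kymograph <- function(kymo) {
  need <- c("time_h", "s_mm", "kappa")
  if (!all(need %in% names(kymo))) {
    abort(sprintf(
      "A kymograph needs columns %s; found: %s.",
      paste(need, collapse = ", "), paste(names(kymo), collapse = ", ")
    ), class = "gravitroot_invalid_format")
  }
  invisible(kymo)
}
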