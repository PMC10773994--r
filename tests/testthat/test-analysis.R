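test_that("steady-state angle summarises the final window", {
  t <- seq(0, 24, 1 / 6)
  const <- tip_trajectory(t, rep(1.5, length(t)))
  ss <- steady_state_angle(const)
  expect_equal(ss$theta_f, 1.5)
  expect_equal(ss$sigma, 0)
  # small sinusoid: mean pi/2, sd ~ amplitude / sqrt(2)
  wig <- tip_trajectory(t, pi / 2 + 0.01 * sin(t))
  ss2 <- steady_state_angle(wig)
  expect_equal(ss2$theta_f, pi / 2, tolerance = 0.002)
  expect_equal(ss2$sigma, 0.01 / sqrt(2), tolerance = 0.2)
  expect_error(steady_state_angle(tip_trajectory(0:4, rep(1, 5))),
               class = "gravitroot_invalid_input")
})

test_that("a simulated Table-scale root approaches alignment with gravity", {
  geom <- table_geometry()
  traj <- clean_trajectory(eta = 1.1, gamma = 1.6, theta0 = 0.02)
  ss <- steady_state_angle(traj)
  # overdamped cohort-mean dynamics: within ~0.15 rad by 24 h, still closing
  expect_lt(abs(ss$theta_f - pi / 2), 0.15)
  mis <- abs(traj$theta_tip - pi / 2)
  expect_lt(tail(mis, 1), mis[which.min(abs(traj$time_h - 12))] / 2)
})

test_that("time to equilibrium matches the exponential closed form", {
  t <- seq(0, 24, 1 / 6)
  traj <- tip_trajectory(t, pi / 2 * (1 - exp(-t)))
  # band entry of pi/2 e^{-t} at sigma = 0.01 pi/2: t* = -ln(0.01)
  tau_eq <- time_to_equilibrium(traj, theta_f = pi / 2,
                                sigma = 0.01 * pi / 2)
  expect_equal(tau_eq, -log(0.01), tolerance = 1 / 6 + 1e-9)
  # same answer under the sustained rule for monotone approach
  tau_eq2 <- time_to_equilibrium(traj, theta_f = pi / 2,
                                 sigma = 0.01 * pi / 2, rule = "sustained")
  expect_equal(tau_eq, tau_eq2)
  # constant trajectory enters immediately under the sigma floor
  const <- tip_trajectory(t, rep(1, length(t)))
  expect_equal(time_to_equilibrium(const, theta_f = 1, sigma = 0), 0)
})

test_that("time to equilibrium is non-increasing in the band width", {
  geom <- table_geometry()
  traj <- clean_trajectory(eta = 1.1, gamma = 0.4, theta0 = 0.02)
  taus <- vapply(c(0.005, 0.01, 0.02, 0.05, 0.1), function(s) {
    time_to_equilibrium(traj, theta_f = pi / 2, sigma = s)
  }, numeric(1))
  expect_true(all(diff(taus) <= 0))
})

test_that("growth-zone length is recovered from model kymographs", {
  geom <- table_geometry()
  gk <- generate_kymograph(geom, mean_sens(), duration = 24)
  est <- estimate_growth_zone(gk$kymograph, tau_eq = 14)
  expect_lte(abs(est$Lgz_mm - geom$growth_zone), 0.0101) # one 10-um cell
  # robust to the detection threshold over [0.03, 0.10]
  ests <- vapply(c(0.03, 0.05, 0.10), function(tf) {
    estimate_growth_zone(gk$kymograph, 14, threshold_frac = tf)$Lgz_mm
  }, numeric(1))
  expect_lt(diff(range(ests)) / mean(ests), 0.1)
})

test_that("growth-zone estimation works for other geometries", {
  geom <- organ_geometry(growth_zone = 0.9, growth_velocity = 0.18)
  sens <- sensitivities(gamma = 0.8, eta = 1.5, geometry = geom)
  gk <- generate_kymograph(geom, sens, duration = 24)
  est <- estimate_growth_zone(gk$kymograph, tau_eq = 14)
  expect_lte(abs(est$Lgz_mm - 0.9), 0.0101)
})

test_that("an unchanging kymograph flags the growth zone as undefined", {
  geom <- table_geometry()
  gk <- generate_kymograph(geom, sensitivities(gamma = 1, eta = 1,
                                               theta0 = pi / 2),
                           duration = 24) # aligned: no bending ever
  expect_warning(est <- estimate_growth_zone(gk$kymograph, tau_eq = 14))
  expect_true(is.na(est$Lgz_mm))
  expect_error(estimate_growth_zone(gk$kymograph, tau_eq = 0.5),
               class = "gravitroot_invalid_input")
})

test_that("shape scores are zero for identical shapes and exact for rotations", {
  s <- seq(0, 3, 0.01)
  straight <- centerline(s, rep(pi / 2, length(s)))
  same <- shape_scores(straight, straight, radius = 0.065)
  expect_equal(same$dist_score, 0)
  expect_equal(same$angle_score, 0)
  rot <- centerline(s, rep(pi / 2 - 5 * pi / 180, length(s)))
  sc <- shape_scores(straight, rot, radius = 0.065)
  expect_equal(sc$angle_score, 5, tolerance = 1e-9)
  expect_gt(sc$dist_score, 0)
})

test_that("shape scores match the chord-length closed form", {
  # straight vertical vs straight 10 deg off, L = 3 mm, r = 0.065 mm:
  # distance at arc s is 2 s sin(5 deg), so the mean is 2 sin(5 deg) L/2 / r
  s <- seq(0, 3, 0.005)
  a <- centerline(s, rep(pi / 2, length(s)))
  b <- centerline(s, rep(pi / 2 - 10 * pi / 180, length(s)))
  sc <- shape_scores(a, b, radius = 0.065)
  expect_equal(sc$angle_score, 10, tolerance = 1e-9)
  expect_equal(sc$dist_score, 2 * sin(5 * pi / 180) * 1.5 / 0.065,
               tolerance = 1e-3)
})

test_that("shape score invariances and the length guard hold", {
  s <- seq(0, 2, 0.01)
  a <- centerline(s, 0.3 * sin(s))
  b <- centerline(s, 0.3 * sin(s) + 0.1)
  base <- shape_scores(a, b, radius = 0.065)
  # joint translation leaves the angle score unchanged
  a2 <- dplyr::mutate(a, x_mm = x_mm + 5, y_mm = y_mm - 2)
  b2 <- dplyr::mutate(b, x_mm = x_mm + 5, y_mm = y_mm - 2)
  expect_equal(shape_scores(a2, b2, radius = 0.065)$angle_score,
               base$angle_score)
  # joint rotation leaves the distance score unchanged
  rot <- function(cl, a0) {
    dplyr::mutate(cl,
      xn = cos(a0) * x_mm - sin(a0) * y_mm,
      yn = sin(a0) * x_mm + cos(a0) * y_mm,
      x_mm = xn, y_mm = yn, theta = theta + a0)
  }
  expect_equal(shape_scores(rot(a, 0.7), rot(b, 0.7), 0.065)$dist_score,
               base$dist_score, tolerance = 1e-12)
  short <- centerline(seq(0, 1.5, 0.01), rep(0, 151))
  expect_error(shape_scores(a, short, radius = 0.065),
               class = "gravitroot_invalid_input")
})

test_that("response_summary assembles the per-root report", {
  geom <- table_geometry()
  traj <- clean_trajectory(eta = 1.1, gamma = 1.6, theta0 = 0.02)
  out <- response_summary(traj, geometry = geom)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$theta_f - pi / 2), 0.15)
  expect_equal(out$nd_growth, geom$growth_rate * out$tau_eq_h)
})
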