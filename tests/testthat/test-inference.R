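test_that("r_squared matches hand arithmetic and flags degeneracy", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0.1, 1.0, 1.9)), 0.99)
  expect_warning(out <- r_squared(c(1, 1, 1), c(1, 1, 1)))
  expect_true(is.na(out))
})

test_that("growth velocity is the least-squares slope of L(t)", {
  t <- seq(0, 24, 1 / 6)
  expect_equal(growth_velocity(t, 0.6 + 0.13 * t), 0.13, tolerance = 1e-12)
  expect_equal(growth_velocity(t, rep(2, length(t))), 0)
  set.seed(3)
  noisy <- 0.6 + 0.13 * t + rnorm(length(t), 0, 0.01)
  expect_lt(abs(growth_velocity(t, noisy) - 0.13) / 0.13, 0.02)
  expect_error(growth_velocity(c(0, 1), c(0, 1)),
               class = "gravitroot_invalid_input")
})

test_that("noise-free trajectories are recovered to relative 1e-3", {
  geom <- table_geometry()
  traj <- clean_trajectory(eta = 1.2, gamma = 1.5, theta0 = 0.1)
  expect_equal(nrow(traj), 145)
  fit <- fit_tip_trajectory(traj, eps0 = geom$growth_rate, geometry = geom)
  expect_true(fit$converged)
  expect_equal(fit$eta, 1.2, tolerance = 1e-3)
  expect_equal(fit$gamma, 1.5, tolerance = 1e-3)
  expect_equal(fit$theta0, 0.1, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_equal(fit$beta, fit$eta * geom$radius / geom$growth_zone)
})

test_that("fitting is deterministic given data and the start list", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 1.6, eta = 1.1, theta0 = 0.05,
                        geometry = geom)
  traj <- generate_trajectory(geom, sens, noise_sigma = 0.02,
                              seed = 21)$trajectory
  f1 <- fit_tip_trajectory(traj, eps0 = geom$growth_rate)
  f2 <- fit_tip_trajectory(traj, eps0 = geom$growth_rate)
  expect_identical(glance(f1), glance(f2))
})

test_that("gamma-pinned fits recover well-specified data and lose otherwise", {
  geom <- table_geometry()
  # data generated with gamma = 0: the restricted fit is well-specified
  traj0 <- clean_trajectory(eta = 1, gamma = 0, theta0 = 0.05)
  f0 <- fit_without_proprioception(traj0, eps0 = geom$growth_rate)
  expect_equal(f0$gamma, 0)
  expect_equal(f0$eta, 1, tolerance = 1e-3)
  expect_gt(f0$r_squared, 0.999999)
  # data generated with gamma = 2: nested-model inequality on noisy replicates
  sens <- sensitivities(gamma = 2, eta = 1, theta0 = 0.05, geometry = geom)
  for (seed in 1:3) {
    traj <- generate_trajectory(geom, sens, noise_sigma = 0.02,
                                seed = seed)$trajectory
    full <- fit_tip_trajectory(traj, eps0 = geom$growth_rate)
    restricted <- fit_without_proprioception(traj, eps0 = geom$growth_rate)
    expect_gt(full$r_squared, restricted$r_squared)
  }
})

test_that("degenerate constant trajectories give a flagged result", {
  traj <- tip_trajectory(seq(0, 24, 1 / 6), rep(pi / 2, 145))
  expect_warning(fit <- fit_tip_trajectory(traj, eps0 = 0.2167))
  expect_false(fit$converged)
  expect_true(is.na(fit$r_squared))
})

test_that("a missing eps0 falls back to the cohort means with a warning", {
  traj <- clean_trajectory()
  expect_warning(fit <- fit_tip_trajectory(traj), "cohort-mean")
  expect_equal(fit$eps0, 0.13 / 0.6)
})

test_that("beta_from_bending recovers beta on noise-free model data", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 1.6, beta = 0.12, geometry = geom)
  sim <- generate_trajectory(geom, sens, noise_sigma = 0)
  bb <- beta_from_bending(sim$trajectory, geom)
  expect_lt(abs(bb - 0.12) / 0.12, 0.05) # 10-min sampling
  # finer sampling tightens the estimate
  sim2 <- generate_trajectory(geom, sens, noise_sigma = 0, dt = 1 / 30)
  bb2 <- beta_from_bending(sim2$trajectory, geom)
  expect_lt(abs(bb2 - 0.12), abs(bb - 0.12))
})

test_that("beta_from_bending is zero for rigid rotation and needs theta_gz0", {
  t <- seq(0, 24, 1 / 6)
  traj <- tip_trajectory(t, 0.1 + 0.05 * t, theta_gz0 = 0.05 * t)
  expect_equal(beta_from_bending(traj, table_geometry()), 0, tolerance = 1e-12)
  expect_error(beta_from_bending(tip_trajectory(t, 0.1 * t), table_geometry()),
               class = "gravitroot_invalid_input")
})

test_that("tidy and glance expose the fit in broom style", {
  geom <- table_geometry()
  fit <- fit_tip_trajectory(clean_trajectory(), eps0 = geom$growth_rate,
                            geometry = geom)
  td <- tidy(fit)
  expect_setequal(td$term, c("gamma", "eta", "theta0", "beta"))
  expect_true(all(td$std.error[td$term %in% c("gamma", "eta", "theta0")] >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
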