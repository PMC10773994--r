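test_that("growth profiles integrate to the tip velocity", {
  geom <- table_geometry()
  for (shape in c("uniform", "triangular")) {
    prof <- growth_profile(shape, geometry = geom)
    expect_equal(prof$vel_fun(geom$growth_zone, geom), geom$growth_velocity,
                 tolerance = 1e-9)
  }
  # a custom profile violating the integral constraint is rejected
  expect_error(
    growth_profile("custom", eps_fun = function(x, g) rep(1, length(x)),
                   geometry = geom),
    class = "gravitroot_invalid_input"
  )
})

test_that("an aligned organ stays straight in the material simulation", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 1, eta = 1, theta0 = pi / 2,
                        geometry = geom) # theta0 = theta_g
  sim <- lagrangian_oracle(geom, sens, t_max = 10, n_material_points = 80)
  expect_equal(max(abs(sim$trajectory$theta_tip - pi / 2)), 0)
})

test_that("material simulation matches the reduced ODE for apical sensing", {
  geom <- table_geometry()
  for (p in list(c(1, 2, -pi / 2), c(0.5, 0, -0.3), c(2, 3, -pi / 2))) {
    sens <- sensitivities(gamma = p[2], eta = p[1], theta0 = p[3] + pi / 2,
                          geometry = geom)
    sim <- lagrangian_oracle(geom, sens, t_max = 10 / geom$growth_rate,
                             n_material_points = 400)
    sol <- solve_root_model(p[1], p[2], p[3], tau_max = 10.001)
    pred <- tip_angle_from_solution(sol, eps0 = geom$growth_rate,
                                    times_t = sim$trajectory$time_h)
    expect_lt(max(abs(pred$theta_tip - sim$trajectory$theta_tip)), 0.01,
              label = sprintf("eta=%g gamma=%g th0t=%g", p[1], p[2], p[3]))
  }
})

test_that("the reduction error shrinks as the oracle step refines", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 2, eta = 1, theta0 = 0, geometry = geom)
  dev_at <- function(n, dt_nd) {
    sim <- lagrangian_oracle(geom, sens, t_max = 5 / geom$growth_rate,
                             n_material_points = n,
                             dt = dt_nd / geom$growth_rate)
    sol <- solve_root_model(1, 2, -pi / 2, tau_max = 5.001)
    pred <- tip_angle_from_solution(sol, eps0 = geom$growth_rate,
                                    times_t = sim$trajectory$time_h)
    max(abs(pred$theta_tip - sim$trajectory$theta_tip))
  }
  coarse <- dev_at(60, 0.1)
  fine <- dev_at(400, 0.01)
  expect_lt(fine, coarse)
  expect_lt(fine, 0.01)
})

test_that("a triangular elongation profile barely changes the tip response", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 1.6, beta = 0.12, geometry = geom)
  uni <- lagrangian_oracle(geom, sens, t_max = 24, n_material_points = 300)
  tri <- lagrangian_oracle(geom, sens,
                           profile = growth_profile("triangular", geometry = geom),
                           t_max = 24, n_material_points = 300)
  expect_lt(max(abs(uni$trajectory$theta_tip - tri$trajectory$theta_tip)),
            0.05)
})

test_that("the oracle records growth-zone base angles and lengths", {
  geom <- table_geometry()
  sens <- sensitivities(gamma = 1.6, eta = 1.1, theta0 = 0, geometry = geom)
  sim <- lagrangian_oracle(geom, sens, t_max = 24, n_material_points = 150)
  tr <- sim$trajectory
  # linear growth: L(t) = L0 + vg t
  expect_equal(tr$length_mm, geom$initial_length + geom$growth_velocity * tr$time_h,
               tolerance = 1e-6)
  # the bending angle theta_tip - theta_gz0 starts and ends near zero
  bend <- tr$theta_tip - tr$theta_gz0
  expect_equal(bend[1], 0, tolerance = 1e-9)
  expect_lt(abs(tail(bend, 1)), 0.1) # growth zone nearly flat again by 24 h
  expect_error(
    lagrangian_oracle(geom, sens, t_max = 1, n_material_points = 10),
    class = "gravitroot_invalid_input"
  )
})
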