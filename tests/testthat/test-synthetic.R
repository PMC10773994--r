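test_that("the default protocol yields 145 samples over 24 h", {
  sim <- generate_trajectory(table_geometry(), mean_sens(), seed = 1)
  expect_equal(nrow(sim$trajectory), 24 * 6 + 1)
  expect_equal(sim$trajectory$time_h[2] - sim$trajectory$time_h[1], 1 / 6)
})

test_that("noise-free samples equal the model trajectory exactly", {
  geom <- table_geometry()
  sens <- mean_sens(theta0 = 0.05)
  sim <- generate_trajectory(geom, sens, noise_sigma = 0)
  sol <- solve_root_model(sens$eta, sens$gamma, sens$theta0_tilde,
                          tau_max = geom$growth_rate * 24 + 1e-6)
  ref <- tip_angle_from_solution(sol, theta0 = sens$theta0,
                                 eps0 = geom$growth_rate,
                                 times_t = sim$trajectory$time_h)
  expect_equal(sim$trajectory$theta_tip, ref$theta_tip)
  # theta_gz0 = theta_tip - k
  k <- sim$trajectory$theta_tip - sim$trajectory$theta_gz0
  expect_equal(k[1], 0, tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_trajectory(table_geometry(), mean_sens(), seed = 99)
  b <- generate_trajectory(table_geometry(), mean_sens(), seed = 99)
  expect_identical(a$trajectory, b$trajectory)
  c <- generate_trajectory(table_geometry(), mean_sens(), seed = 100)
  expect_false(identical(a$trajectory$theta_tip, c$trajectory$theta_tip))
})

test_that("seeded generation restores the caller's RNG state", {
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  invisible(generate_trajectory(table_geometry(), mean_sens(), seed = 7))
  expect_identical(runif(1), before)
})

test_that("synthetic kymographs close the loop with the growth-zone estimator", {
  geom <- table_geometry()
  gk <- generate_kymograph(geom, mean_sens(), duration = 24, seed = 2)
  est <- estimate_growth_zone(gk$kymograph, tau_eq = 14)
  expect_lte(abs(est$Lgz_mm - geom$growth_zone), 0.0101)
  # aligned parameters give an all-zero field
  gk0 <- generate_kymograph(geom, sensitivities(gamma = 1, eta = 1,
                                                theta0 = pi / 2))
  expect_equal(max(abs(gk0$kymograph$kappa)), 0, tolerance = 1e-12)
})

test_that("an empty cohort is valid and has the full schema", {
  coh <- generate_cohort(cohort_spec(n_roots = 0))
  expect_equal(nrow(coh), 0)
  expect_true(all(c("root", "beta", "gamma", "eta", "theta0",
                    "trajectory") %in% names(coh)))
})

test_that("cohorts are reproducible by seed and draw positive parameters", {
  spec <- cohort_spec(n_roots = 8, seed = 4)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$beta, b$beta)
  expect_identical(a$trajectory[[3]], b$trajectory[[3]])
  d <- generate_cohort(cohort_spec(n_roots = 8, seed = 5))
  expect_false(identical(a$beta, d$beta))
  expect_identical(names(a), names(d))
  expect_true(all(a$beta > 0 & a$gamma >= 0 & a$growth_zone > 0 &
                    a$theta0 >= 0))
  expect_equal(a$eta, a$beta * a$growth_zone / a$radius)
})

test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(duration = 1, dt = 0.5),
               class = "gravitroot_invalid_input")
  expect_error(cohort_spec(means = c(beta = 0.1)),
               class = "gravitroot_invalid_input")
  expect_error(cohort_spec(means = c(beta = -1, gamma = 1, r = 0.065,
                                     Lgz = 0.6, vg = 0.13)),
               class = "gravitroot_invalid_input")
})

test_that("cohort directories contain one file per root plus the truth table", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_roots = 3, seed = 6), dir = dir)
  files <- list.files(dir)
  expect_setequal(files, c("root_001.csv", "root_002.csv", "root_003.csv",
                           "truth.csv"))
  back <- read_trajectory(file.path(dir, "root_002.csv"))
  expect_equal(back$theta_tip, coh$trajectory[[2]]$theta_tip,
               tolerance = 1e-12)
})
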