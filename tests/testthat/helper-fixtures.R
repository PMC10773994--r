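# Shared fixtures: cohort-mean geometry and a couple of canonical parameter
# sets used across files. All synthetic data are generated in code.

table_geometry <- function() organ_geometry()  # r=0.065, Lgz=0.6, vg=0.13

mean_sens <- function(theta0 = 0) {
  sensitivities(gamma = 1.6, eta = 1.1, theta0 = theta0,
                geometry = table_geometry())
}

# Noise-free sampled trajectory from known parameters.
clean_trajectory <- function(eta = 1.2, gamma = 1.5, theta0 = 0.1,
                             geometry = table_geometry(), dt = 1 / 6,
                             duration = 24) {
  sens <- sensitivities(gamma = gamma, eta = eta, theta0 = theta0,
                        geometry = geometry)
  generate_trajectory(geometry, sens, noise_sigma = 0, dt = dt,
                      duration = duration)$trajectory
}
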