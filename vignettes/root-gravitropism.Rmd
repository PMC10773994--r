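---
title: "Modelling root gravitropism: apical sensing with a finite growth zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling root gravitropism: apical sensing with a finite growth zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gravitroot)
library(dplyr)
```

## The model

When a root is tilted away from the direction of gravity it bends back by
differential growth. Two physiological facts distinguish roots from aerial
organs and shape the model implemented here:

* **Gravisensing is apical.** The inclination-sensitive statocytes sit in
  the columella of the root cap, an order of magnitude shorter than the
  growth zone. The whole growth zone therefore responds to a single input,
  the tip angle $\theta_{tip}(t)$, rather than to the local inclination
  $\theta(s,t)$.
* **Growth is subapical and linear.** Only a zone of fixed length $L_{gz}$
  behind the tip elongates. Curvature can change only there; material that
  leaves the growth zone keeps its curvature forever, so the organ length
  grows linearly, $L(t) = L_0 + L_{gz}\,\dot\varepsilon_0 t$, and the mature
  zone is a frozen record of the tip's history.

Within the growth zone the curvature $\kappa$ of a material element obeys

$$\frac{r}{\dot\varepsilon_0}\frac{D\kappa}{Dt}
  = -\beta\,\sin(\theta_{tip} - \theta_g) - \gamma\, r\,\kappa ,$$

where $r$ is the organ radius, $\theta_g$ the stimulus direction
($\pi/2$ for a horizontally tilted root in our angle convention),
$\beta$ the *gravitropic sensitivity* (gain from sensed inclination to
curvature production) and $\gamma$ the *proprioceptive sensitivity* (gain of
the curvature-straightening response). $D/Dt = \partial_t + v\,\partial_s$
is the material derivative under the growth velocity
$v(s,t)=\int_0^s\dot\varepsilon\,du$. Elasticity and external forces are
neglected: the roots this describes grow against minimal resistance and
their self-weight is negligible.

Because the apical signal is shared by the whole growth zone, the
growth-zone curvature is spatially uniform, and the dynamics reduce
exactly to a scalar integro-differential equation. In nondimensional
variables — growth-zone angle $k=L_{gz}\kappa_{gz}$, time
$\tau = \dot\varepsilon_0 t$ (organ growth in units of $L_{gz}$), effective
sensitivity $\eta = \beta L_{gz}/r$ — it reads

$$-\tfrac{1}{\eta}(k' + \gamma k) =
  \sin\!\Big(\int_0^\tau k\,d\tau' + k + \tilde\theta_0\Big),
  \qquad \tilde\theta_0 = \theta_0 - \theta_g ,$$

and the tip angle follows as
$\theta_{tip} = \theta_0 + \int_0^\tau k\,d\tau' + k$. The integral is the
angle stored in the mature zone; it is the *passive orientation drift* term
that lets a growing organ carrying fixed curvature keep turning, and it is
the source of overshoot.

### How the solver is organised

`solve_root_model()` integrates the **augmented first-order system**
$K' = k$, $k' = -\eta\sin(K + k + \tilde\theta_0) - \gamma k$ with
$K(0)=k(0)=0$ (adaptive `lsoda`, `rtol = 1e-8`, `atol = 1e-10`). One could
instead differentiate once more and divide, obtaining a second-order ODE in
$k$ alone with an $\arcsin$-derived square-root denominator
$\sqrt{\eta^2 - (k'+\gamma k)^2}$; we deliberately do not solve that form,
because at the headline initial condition of a horizontal tilt
($\tilde\theta_0 = -\pi/2$) the denominator vanishes at $\tau = 0$ together
with the numerator. The augmented system is regular everywhere, recovers
the stated initial slope $k'(0) = -\eta\sin\tilde\theta_0$ automatically,
and the second-order form is kept as an a-posteriori consistency check
(`residual_eq8()`, residuals at the solver-tolerance level, the degenerate
initial instant masked).

`lagrangian_oracle()` is an independent check of the reduction itself: a
material-point discretisation of the transport equation above (midpoint
scheme, default step $\Delta\tau \le 0.25/(\eta+\gamma+1)$ capped at 0.025,
material grid refined where growth stretches it beyond 1.5 cells).
Material points advect with the growth velocity; since curvature production
is proportional to the local elongation rate, freezing in the mature zone
happens automatically. The two solvers agree to a few $10^{-4}$ rad in
$\theta_{tip}$ across the tested $(\eta,\gamma,\tilde\theta_0)$ grid at 400
material points, and the oracle also supports *local* sensing and
non-uniform elongation profiles (e.g. triangular), which we use to show
the uniform-rate assumption is benign (tip-angle difference $<0.05$ rad).

```{r solve-example}
sol <- solve_root_model(eta = 1.1, gamma = 1.6, theta0_tilde = -pi / 2,
                        tau_max = 5.2)
tail(tidy(sol), 3)
```

### Comparison models

Two simpler growth treatments bracket the root model:

* **AC model** (`solve_ac_model()`): no explicit growth, a single uniform
  curvature state, $k' = -\eta\sin(k+\tilde\theta_0) - \gamma k$. With
  $\gamma>0$ it stalls at the balance point
  $\eta\sin(k^*+\tilde\theta_0) = -\gamma k^*$ (for
  $\eta=\gamma=1$ and a horizontal tilt, $k^* = \cos k^*\approx 0.739$,
  i.e. $\sim42^\circ$, short of vertical); it aligns only when $\gamma=0$.
* **Exponential-growth ACE** (`solve_ace_exponential()`): the growth zone
  spans the whole organ, which therefore grows exponentially. The default
  implementation keeps the cited model's *local* sensing and solves the
  fixed-dimension material-coordinate system
  $\dot q(s_0) = -\eta_0\sin(\theta(s_0)-\theta_g) - \gamma q$,
  $\theta(s_0) = \theta_0 + e^\tau\!\int_0^{s_0} q$, with a stiff solver.
  The exponentially growing lever arm amplifies passive orientation drift:
  the tip overshoots the stimulus for every tested $\gamma$ and, for
  moderate proprioception, keeps oscillating across the solved horizon.
  An `sensing = "apical"` variant collapses to the scalar ODE
  $\hat q' = -\eta(\tau)\sin(e^\tau \hat q + \tilde\theta_0) - \gamma\hat q$;
  since the analytic treatment behind the published comparison figures is
  not available to us, the `eta_definition` flag exposes both readings of
  the gravitropic gain (fixed at the initial length, or scaling with the
  instantaneous length). We found the apical variant *settles* onto the
  stimulus once $e^\tau$ is large (the restoring gain grows without bound
  while the drift stays bounded) and for $\gamma>1$ approaches alignment
  from below without crossing — so it cannot reproduce the sustained
  oscillations expected of whole-organ growth, which is why local sensing
  is the default. Even under local sensing, strong proprioception
  ($\gamma \gtrsim 5$) straightens the organ fast enough that the
  oscillation amplitude decays below $10^{-2}$ rad well before $\tau=10$;
  we believe no faithful formulation avoids this, and the package makes no
  attempt to.

### The damped-oscillator picture

Linearising near alignment gives
$k'' + (\eta+\gamma)k' + \eta k = 0$: a damped harmonic oscillator with
natural frequency $\omega_0=\sqrt\eta$, attenuation $\Gamma=\eta+\gamma$,
quality factor $Q = \sqrt\eta/(\eta+\gamma)$ and critical proprioception
$\gamma_{crit} = 2\sqrt\eta - \eta$ (`oscillator_quantities()`,
`small_angle_solution()`). Underdamping of $k$ ($\gamma<\gamma_{crit}$)
corresponds to oscillatory regrowth.

One subtlety we document because it is easy to trip over: *overshoot of the
tip* is not exactly equivalent to underdamping. The tip angle adds the
mature-zone integral to $k$, and its slow-mode coefficient changes sign at
$\gamma = 1$, not at $\gamma_{crit}$. For $\eta \le 1$ the two boundaries
coincide closely enough that tip crossings switch at $\gamma_{crit}$ (we
verify this within a 0.05 step in $\gamma$), but for $\eta > 1$ there is a
window $\gamma_{crit} < \gamma < 1$ in which $k$ relaxes monotonically yet
the stored curvature still carries the tip slightly past the stimulus
before it settles back. `overshoots()` therefore detects crossings by
event location with an amplitude guard (excursions must exceed
$10^{-10}$ rad) so that the asymptotic approach, which dithers at the
integrator's noise floor, is never miscounted.

## Estimating sensitivities from data

`fit_tip_trajectory()` fits observed $\theta_{tip}(t)$ series by bounded
Levenberg–Marquardt least squares over $\{\gamma, \eta, \theta_0\}$, with
$\theta_g$ fixed. $\theta_0$ is bounded positive because
$\tilde\theta_0 = \theta_0-\theta_g$ and $-\theta_0-\theta_g$ produce the
same initial condition for a horizontal tilt, so the sign of $\theta_0$ is
not identifiable. Defaults that matter:

* bounds $\gamma\in[0,20]$, $\eta\in(10^{-4},20]$,
  $\theta_0\in(0,\pi/2)$ — generous relative to every estimate we produce;
* a deterministic 8-point multistart on a coarse $(\eta,\gamma)$ grid
  ($\eta \in \{0.3,1,3,10\} \times \gamma \in \{0.5,5\}$, $\theta_0$
  started at 0.01 rad), because the loss surface has local minima when the
  data barely constrain $\gamma$; the best final sum of squares wins and
  results are reproducible given the data;
* $\dot\varepsilon_0$ is taken from the supplied geometry
  ($v_g/L_{gz}$); with no geometry at all the cohort means are used with a
  warning.

`fit_without_proprioception()` pins $\gamma=0$; comparing its $R^2$
against the full fit's (nested models, same loss) quantifies how much the
data demand proprioception. `beta_from_bending()` is the independent
estimator $\beta_{bend} = \max_t \frac{d}{dt}(\theta_{tip}-\theta_{gz0})\,
r/v_g$: on noise-free model data with a horizontal tilt the maximal bending
rate is $\dot\varepsilon_0\eta$ at $t=0$, so $\beta_{bend}=\beta$ exactly
in the continuum. The derivative is taken with a Savitzky–Golay filter
(order 2, 5 samples — 50 min of the 10-min protocol, comfortably shorter
than the $\sim(\dot\varepsilon_0\Gamma)^{-1}\approx 1.7$ h response
timescale) because the maximum of a raw finite-difference series is
upward-biased under noise. A residual upward bias remains on noisy data —
the max of ~145 smoothed slopes rides the noise envelope — which is worth
keeping in mind when comparing $\beta_{bend}$ with the fit-based
$\beta$; the same ordering (bending estimate above fit estimate) is seen
in the experimental estimates this package emulates.

```{r fit-example}
geom <- organ_geometry()   # r = 0.065 mm, Lgz = 0.6 mm, vg = 0.13 mm/h
sens <- sensitivities(gamma = 1.6, eta = 1.1, theta0 = 0.05,
                      geometry = geom)
sim <- generate_trajectory(geom, sens, noise_sigma = 0.02, seed = 1)
fit <- fit_tip_trajectory(sim$trajectory, geometry = geom)
glance(fit)
```

## Trajectory and kymograph estimators

* `steady_state_angle()`: mean and SD of $\theta_{tip}$ over the last 5 h.
* `time_to_equilibrium()`: time for the tip to approach
  $\theta_f \pm \sigma$. Two band rules are provided. The default,
  `"first_entry"`, takes the first sample inside the band; the alternative
  `"sustained"` requires every later sample to stay inside. We default to
  first entry on estimator-consistency grounds: with independent angle
  noise of the same scale as $\sigma(\theta_f)$, a late sample leaves a
  $\pm 1\sigma$ band with probability $\approx 0.32$, so the sustained rule
  almost surely returns (nearly) the record length on any noisy record,
  which is incompatible with finite equilibrium times well inside a 24 h
  record. $\sigma$ is floored at $10^{-3}$ rad so noiseless synthetic
  records define a non-empty band.
* `estimate_growth_zone()`: computes $|\partial\kappa/\partial t|$ on the
  kymograph grid with *forward* time differences (so frozen cells are
  exactly zero and the growth-zone boundary is not smeared), re-indexes by
  distance from the tip $d = L(t)-s$ (linear interpolation onto a 10 µm
  grid, cells kept when sampled in at least half the retained times),
  averages over $t < \tau_{eq}$, and returns the largest $d$ at which the
  profile exceeds 5% of its spatial mean. Magnitudes are averaged because
  bending reversals would cancel in a signed mean. On model kymographs the
  estimate is exact to one grid cell and varies by <10% across thresholds
  0.03–0.10.
* `shape_scores()`: resamples two centerlines on a common arc-length grid
  from the base (10 µm spacing, truncated to the shorter organ, lengths
  within 10% of each other enforced) and reports the mean point distance
  normalised by the radius, and the mean absolute tangent-angle difference
  in degrees.

```{r kymo-example, fig.alt = "Curvature kymograph of a simulated root"}
gk <- generate_kymograph(geom, sens, duration = 24)
plot_kymograph(gk$kymograph)
estimate_growth_zone(gk$kymograph, tau_eq = 14)$Lgz_mm
```

## What the synthetic generator emulates — and what it does not

`generate_trajectory()`/`generate_cohort()` emulate the gravistimulation
protocol behind the estimates above: horizontal tilt
($\theta_g=\pi/2$, $\theta_0$ half-normal with 0.05 rad scale emulating
placement scatter), pictures every 10 min for 24 h (145 samples), per-root
geometry and sensitivities drawn as independent truncated normals at the
measured cohort means and spreads ($r = 65\pm11$ µm,
$L_{gz}=0.60\pm0.14$ mm, $v_g=0.13\pm0.04$ mm/h, $\beta=0.12\pm0.06$,
$\gamma=1.6\pm1.0$), and additive i.i.d. Gaussian angle noise with
$\sigma = 0.02$ rad ($\approx 1.1^\circ$), a magnitude under which the
$R^2>0.9$ screening used on real data remains attainable. All randomness
flows through one seed; generation is bit-identical given the seed and
restores the caller's RNG state.

Passing the package's recovery tests therefore shows that the inference
machinery is unbiased and well-identified *under the model with this noise
process*. Real records additionally contain autocorrelated tracking error,
centerline-extraction artefacts and genuine model misfit; that is why
roughly a quarter of experimental trajectories fail the $R^2>0.9$ screen
while essentially all synthetic ones pass it, and why the synthetic
$\gamma=0$ screen passes more often than the experimental 5%. The
synthetic cohort quantifies estimator behaviour; it does not reproduce
real-data pass rates.

Truncation to positive values also shifts the effective population means
slightly above the nominal ones (e.g. mean $\gamma \approx 1.69$ rather
than 1.6, mean $\eta \approx 1.2$ rather than 1.1); cohort-level summaries
computed by `scripts/acceptance.R` inherit that shift and should be read
against the generating distribution, not the nominal means alone.

## Numerical choices and degenerate inputs

* Internal units are mm, hours, radians; conversions happen only in the
  I/O layer (`read_trajectory()` honours declared degree/minute units).
* Curvature differentiation: three-point central differences inside,
  second-order one-sided stencils at the ends, on possibly non-uniform
  grids; shape integration is cumulative trapezoidal; the
  $\theta\to\kappa\to\theta$ round trip converges at second order.
* Simulation horizon: $\tau_{max}=10$ by default, about three times the
  typical nondimensional response duration ($\approx 3$).
* Constant trajectories ($SS_{tot}=0$) yield flagged fits
  (`converged = FALSE`, $R^2$ undefined) rather than errors; kymographs
  with no curvature change flag the growth zone as undefined; masked
  kymograph cells (beyond the tip) are omitted, never zero-filled.
* Problem sizes used in the test suite: 400 material points and
  $\tau \le 10$ for oracle comparisons; 100 seeded replicates at the
  experimental design for the recovery study; 114-root cohorts for
  population-level checks.

## Known limitations

* Planar centerlines only; no torsion, elasticity, or substrate
  interaction — consistent with the modelling assumptions, but a real
  limitation for roots growing in soil.
* The exponential-growth comparison model is a numerical stand-in
  constrained by qualitative behaviour (overshoot, sustained oscillation,
  no convergence of fits), not by a published closed form.
* $\beta_{bend}$ retains an upward noise bias; treat it as an upper
  companion to the fit-based estimate.
* The trajectory reader is schema-flexible (column aliases, unit
  metadata, hint overrides) but has only been exercised against files this
  package writes; one adapter function isolates any changes a new external
  schema would require.
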