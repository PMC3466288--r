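---
title: "Learning force and impedance across movements: the model behind impedadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning force and impedance across movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

impedadapt simulates how a human arm learns to move in novel mechanical
environments — both stable velocity-dependent force fields and unstable,
divergent ones — by adapting feedforward muscle activation trial by trial
while a fixed, delayed feedback pathway keeps movements roughly on track.
This vignette describes the model, its assumptions, the tunable parameters
and the numerical choices, and what the simulated experiments do and do not
show about real motor behaviour.

## The plant: a planar two-joint, six-muscle arm

The skeleton is a standard rigid two-link chain moving in the horizontal
plane (no gravity): shoulder at the origin, x to the subject's right, y
away from the body. Configuration-dependent inertia, Coriolis/centripetal
torques and a small constant joint viscosity follow the textbook planar
two-link equations (`mass_matrix()`, `coriolis_matrix()`,
`forward_dynamics()`).

Six muscles act through constant moment arms (`muscle_geometry()`): a
shoulder antagonist pair, an elbow pair, and a biarticular pair spanning
both joints. Muscle lengths are linearised around a reference posture, so
length changes are `-t(A) %*% (q - q_ref)`. Muscles only pull; tension is

    T_i = max(0, T0*u_i + (k0 + k1*u_i)*(l_i - lambda_i)
                 + (b0 + b1*u_i)*(ldot_i - lambdadot_i))

with activation `u_i >= 0`. Both stiffness `k(u)` and viscosity `b(u)`
increase affinely with activation, which is what makes co-activation of an
antagonist pair raise joint impedance without producing net torque. The
visco-elastic rest length `lambda_i(t) = l_r,i(t) - rho*u_i` travels with
the descending reference command: muscle impedance acts instantaneously
around the intended (for the unstable task: the habitual mean) trajectory,
in the spirit of equilibrium-trajectory control. This choice is load-bearing.
If instead the elastic reference is anchored at a fixed posture, any
co-activation drags the limb toward that posture, and learned impedance
destabilises rather than stabilises movements away from it.

Motor noise is signal-dependent: each muscle receives an independent
Gaussian perturbation whose standard deviation is `coef * u_i`, low-pass
filtered at 10 Hz to mimic the bandwidth of motor-unit force (white noise
at the 1 ms simulation grid would produce unphysically fast force
fluctuations). The default coefficient (0.02) corresponds to a
few-percent coefficient of variation at the net-force level. It matters
in two opposite ways: noise is the seed of the initial left/right
divergence in the unstable task and of noise-driven co-activation
learning, but it also sets the ceiling of the trial-to-trial velocity
correlation used as the learning metric in the granularity experiment
(at a coefficient of 0.05 that ceiling drops to about 0.85, masking the
effect being measured).

## The controller: feedforward plus delayed V-shaped feedback

The motor command is `u = max(0, u_ff) + u_fb`. The feedback command is a
piecewise-linear, V-shaped function of the *delayed sliding error*
`eps_i(t) = e_i(t - delta) + kappa * edot_i(t - delta)`, where
`e_i = l_i - l_r,i` is the muscle length error against the reference plan:
both stretch and shortening increase activation, stretch with twice the
slope (defaults 30 and 15 per metre). The V-shape means any perturbation
co-activates both muscles of a crossed antagonist pair — a feedback
response observed when postural stability matters — while the slope
asymmetry yields a net restoring action. The neural delay is 60 ms by
default (configurable up to 200 ms); the velocity weighting `kappa`
(50 ms) is a filter-form choice, since only the presence of both length
and velocity information in the error signal is constrained.

Reference trajectories are minimum-jerk: point-to-point reaches with a
short terminal hold, and circles drawn with a minimum-jerk angular
profile, so circular movements start and end at rest and sweep through
the same range of speeds as the reaches. This matters for
generalization: with a constant-speed 300 ms lap, every circle state is
roughly three times faster than any reach state, and nothing learned on
reaches can transfer to the circle through a state-space representation.

## Trial-by-trial learning

Between trials, the feedforward parameters `w >= 0` of any
linear-in-parameters primitive `u_ff = Phi(x) w` are updated by

    w <- max(0, w + eta*Q*dt * sum_t Phi(x_t)' v(s_t) - gamma)

where `s_t = e(t) + kappa*edot(t)` is the delay-compensated sliding error
(the error paired with the state at which it could have been prevented)
and `v` is the V-shaped drive. The drive decomposes exactly into a signed
reciprocal term proportional to `s` (a force opposing systematic error on
the next trial), a non-negative co-activation term proportional to `|s|`
(impedance raised in response to deviation of either sign), and the
uniform decay `gamma` that removes superfluous (co-)activation — weakly
supported parameters reach zero first, a winner-take-all pruning. The
update is the exact negative gradient of an error-potential-plus-effort
objective (`error_potential()`, `cost()`), which the test suite verifies
against central finite differences. With pure noise and no systematic
error the reciprocal term averages out and co-activation accumulates:
variability itself buys impedance.

In the unstable (divergent-field) task, on-line control is referenced to
the running mean of the last five successful trials — the convention for
tasks where the "intended" trajectory is the habitual one — while the
learning drive is referenced to the planned straight path. Both choices
are necessary: mean-referenced on-line impedance stabilises around what
the arm actually does, but if learning is also mean-referenced the model
settles contentedly into a curved path (the error from its own mean is
zero there) and never straightens. Successful trials must reach the end
circle without touching the safety barrier.

## The state-space representation

The feedforward map is a Gaussian radial-basis-function network over the
4-D joint state (angles and velocities). States are standardized (the
scaling frozen into the network) so positions and velocities are
commensurable. Centers are placed by restarted K-means on the states of
performed null-field movements pooled with the planned trajectories —
performed movements, because early unpracticed trials stray far from the
plan, and the activation fields must cover those states for learning to
engage at all. The neuron count is searched outward from 20 within
[3, 80] for the smallest count whose best-of-restarts clustering places
95% of states within a coverage radius (0.85 standardized units) of a
centroid, under a total Lloyd-iteration budget of 2000 (read as the
budget of the whole selection stage; Lloyd itself caps at 100 iterations
per restart). On the packaged experiments this yields roughly 10-35
neurons. Widths are the per-dimension cluster extents ("include all data
within the cluster") times a scaling factor chosen so adjacent fields
overlap — 1.5 along positions and 2.5 along velocities, the wider
velocity tuning being what lets learning acquired at reach speeds extend
toward faster states. Only the weights adapt afterwards; centers and
widths are frozen, which is the point of the granularity experiment: a
single representation must cope with fields of every spatial complexity.

## The environments

* **NF** — null field.
* **VF** — `F = B %*% v`. The default gain matrix is the classic
  anisotropic viscous matrix `[[-10.1, -11.2], [-11.2, 11.1]]` N s/m from
  the source reaching experiments. A pure curl is isotropic on a circle
  and cannot elongate it; the anisotropic matrix reproduces the reported
  vertical elongation on first exposure.
* **VFk** — a curl whose gain is modulated by `sin(k * theta)` of the
  planned movement direction, `k` in {1, 2, 4}; amplitude 70 N s/m. The
  modulation form is a documented choice with the required 2*pi/k
  periodicity; the amplitude is calibrated so the field is strong enough
  relative to the arm's practiced impedance for adaptation differences
  between k values to be measurable.
* **DF** — divergent field: force normal to the start-goal line,
  proportional to the lateral deviation (600 N/m), zero inside the
  2.5 cm start/end circles, replaced by 50 N s/m lateral damping beyond
  the 5 cm safety barrier.

Field gains are deliberate calibrations: the source text renders all
numeric gain values as figures, so the package identifies them once from
the cited experiments' ranges and the reported qualitative regimes, and
prints them in every configuration (`default_config()`, the shipped YAML).

## The three experiments

`run_generalization()` (movement generalization): the network is sized on
null-field data from eight 12 cm/300 ms reaches spanning 360 degrees plus
a 10 cm circle; a null-field practice phase (100 reaches + 100 circles,
randomized) teaches the arm its own dynamics — necessary for free-condition
circles to be round in the first place. Two arms then adapt to the VF for
100 trials, one directly on circles, one on reaches only; circle probes
(5 per phase) measure the horizontal/vertical extent ratio in the free
condition, on first exposure, after adaptation in the field, and in
catch trials with the field silently removed.

`run_granularity()` (granularity): sixteen directions, 80 null-field then
160 field trials per field variant with identical network
hyperparameters; the learning curve is the correlation of each trial's
movement-window velocity time series with the same-direction null-field
template, smoothed by a trailing 20-movement moving average.

`run_impedance()` (impedance learning): two 25 cm/600 ms movements 35
degrees apart (start 18 cm ahead of the shoulder, the second direction
rotated clockwise), randomly intermixed in the DF for 300 trials.
Endpoint stiffness ellipses are computed before and after learning from
the mid-movement activation via
`K_e = J^-T A diag(k(u) + c(u)*sbar) A' J^-1`, which carries both the
intrinsic (activation-dependent) and the reflex (V-slope) contributions;
the analytic form is validated against a static force-probe oracle. The
task geometry and the biarticular moment arms (40/25 mm) were chosen
once, from an analytic scan of achievable stiffness orientations, so that
a lateral co-activation pattern *can* orient the ellipse along the
instability for both movement directions — with symmetric biarticular
arms and a mid-workspace start this is geometrically impossible for the
straight-ahead movement no matter what is learned.

## Numerical choices and degenerate inputs

Fixed-step RK4 at 1 ms with activation held within a step; delays and
logging live on the same grid. A compiled inner loop carries whole
trials; a step-by-step R implementation of the identical loop is kept and
tested against it to machine precision. Trials whose hand speed exceeds
8 m/s are aborted, flagged, and excluded from learning. Empty K-means
clusters are re-seeded from the farthest point. Singleton clusters get a
floor width. Tension rectification, weight clipping and the V-shape are
the only non-smooth elements; the gradient-oracle test stays in the
interior where the objective is differentiable.

Problem sizes were chosen so a full experiment runs in seconds on one
core: 5 seeds x (200 practice + 100 + 100 training trials) for the
generalization protocol, 5 x 240 trials per field for granularity,
3 x (100 + 300) for the unstable task.

## What the simulations do and do not show

The generator emulates trial-by-trial kinematics of a planar arm under
idealised conditions: minimum-jerk intentions, linearised muscle
geometry, affine visco-elasticity, stationary noise, and environments
applied exactly at the hand. It does not model reflex-circuit physiology,
tendon or force-velocity dynamics, posture-dependent moment arms,
visuomotor corrections, or modulation of the feedback gains themselves —
adaptation here is purely of the feedforward command. Quantities that
depend on those mechanisms (EMG time courses, reflex gain changes,
3-D kinematics) are outside what passing tests can support. Known
limitations within scope: reach-to-circle transfer is partial and
seed-variable (the circle's fast mid-lap states lie at the edge of the
practiced state distribution), the late stages of long unstable-field
runs can accumulate more co-activation than the decay removes, and the
stiffness-orientation result depends on the muscle geometry being able to
express lateral stiffness at the task posture at all.
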