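---
title: "Model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvrsim` simulates a closed-loop, lumped-parameter (zero-dimensional) model
of the human cardiovascular system, optionally coupled to a minimal model of
respiratory mechanics, as a system of ordinary differential equations. This
vignette describes the model in the package's own terms: the governing
equations, the parameters that matter and their defaults, the numerical
design, and the limits of what the bundled tests demonstrate.

## The cardiovascular loop

Six compartments are connected in a ring: pulmonary artery (pa), pulmonary
vein (pu), left ventricle (lv), aorta (ao), vena cava (vc) and right
ventricle (rv). Flow passes rv → pa → pu → lv → ao → vc → rv; the four
connections into and out of the ventricles carry valves (pulmonary,
mitral, aortic, tricuspid), the other two (pulmonary and systemic
circulation) are plain resistances. Each vessel compartment is a linear
elastance, `P = E (V - V_d)`, with pleural pressure added for the two
intrathoracic (pulmonary) vessels.

Each ventricular wall interpolates between two pressure–volume laws with a
periodic activation `e(t)` in [0, 1] (time-varying elastance):

* end-systolic: `P_es(V) = E_es (V - V_d)` (linear, maximal stiffness),
* end-diastolic: `P_ed(V) = P_0 (exp(lambda (V - V_0)) - 1)` (passive
  exponential filling curve),
* instantaneous: `P = e P_es + (1 - e) P_ed`.

The activation is a Gaussian pulse
`e(t) = A exp(-B ((t mod T) - C)^2)` with period `T = 60/HR`; `A = 1`
bounds it in [0, 1] and `C = T/2` makes it continuous across the cycle
boundary, leaving the width `B` (80 s^-2 in the presets) and the heart
rate as the only free shape parameters.

### Ventricular interaction

The two ventricles couple through the septum and share a passive
pericardial sac. Three virtual free-wall volumes are used:
`V_lvf = V_lv - V_spt`, `V_rvf = V_rv + V_spt`, and the septum volume
`V_spt` itself, defined implicitly by the pressure balance

```
f(V_spt) = P_lvf(V_lv - V_spt) - P_rvf(V_rv + V_spt) - P_spt(V_spt) = 0.
```

Because every wall law has `dP/dV > 0` for physical parameters, `f` is
strictly decreasing and the root is unique. The package solves this with
Newton–Raphson using the analytic derivative, warm-started from the last
accepted value; a closed-form alternative replaces the exponential EDPVR
by its tangent (`P_0 lambda (V - V_0)`) in the balance only, giving the
quotient implemented in `solve_septum_linearized()`. In linearised mode
all *reported* pressures still use the full nonlinear laws — the
linearisation enters the septum solution alone. The two modes differ
noticeably during the diastole that follows an inhalation, when the
nonlinear solve predicts a markedly larger septal deflection into the
left ventricle.

### Valve laws

Two valve models are provided:

* non-inertial: `Q = max((P_up - P_down)/R, 0)` — a check valve that
  conducts only down the pressure gradient;
* inertial ('open on pressure, close on flow'): the flow is an ODE state,
  `dQ/dt = (P_up - P_down - Q R)/L` while `Q > 0` or `P_up > P_down`, and
  `0` otherwise, so flow persists briefly against an adverse gradient on
  its inertia.

The mass balance ramps each valved flow (`max(Q, 0)`) so that the tiny
negative flows the inertial law acquires from finite solver tolerances do
not propagate; the valveless pulmonary/systemic flows stay signed because
backflow there is physical. Every connection flow appears exactly once as
an inflow and once as an outflow, so the summed volume derivative is
identically zero and total blood volume is a linear invariant — conserved
exactly by any Runge–Kutta step, up to rounding.

## Respiratory coupling

Pleural pressure, constant (−4 mmHg) in the pure cardiovascular model,
becomes dynamic when the respiratory component is attached:

* a planar Lienard oscillator `dx/dt = alpha f(x, y)`,
  `dy/dt = alpha x`, `f = (a y^2 + b y)(x + y)` acts as the central
  respiratory pattern generator; `y` is the pattern output;
* respiratory muscle pressure integrates the pattern,
  `dP_mus/dt = lambda_mus y + mu` (original) or
  `... - beta P_mus` (stabilized);
* passive mechanics: intrathoracic blood volume
  `V_bth = V_lv + V_rv + V_pu + V_pa`, thoracic volume
  `V_th = V_bth + V_alv`, pleural pressure
  `P_pl = P_mus + E_cw (V_th - V_th0)`, and alveolar airflow
  `dV_alv/dt = -(P_pl + E_alv V_alv)/(R_ca + R_ua)`.

The original formulation also subtracts a Hering–Breuer reflex term
`HB dV_alv/dt` inside the oscillator's hidden state. The stabilized
variant drops it and instead applies integral feedback (`beta`, default
0.1 s^-1) to the muscle pressure. The two switches (`HB`, `beta`) are kept
independent in `respiratory_params()` so the canonical configurations
(HB = 1, beta = 0) and (HB = 0, beta = 0.1) and anything between are
expressible.

### Why stabilization is needed, and what our implementation shows

Without the leak term, `P_mus` is a pure integral of `lambda_mus y + mu`,
and it is stationary only if the oscillator's cycle-mean pattern equals
`-mu/lambda_mus = -2/3` exactly. With the shipped parameters the limit
cycle's mean is about −0.85 (−0.74 once the reflex coupling acts), so the
uncorrected model drifts at roughly −0.11 mmHg s^-1 — the breath-mean
muscle pressure falls and the alveolar volume climbs without bound. The
literature this model descends from reports the same instability with the
*opposite* direction (muscle pressure rising, lung volume falling); the
source that first printed these respiratory parameters is known to have
carried unit errors in the airway resistances and resting thoracic
volume, so its effective oscillator sat on the other side of the
stationarity point. The drift's existence, its magnitude's dependence on
the distance between the cycle mean and `-mu/lambda_mus`, and its removal
by the integral correction are all reproduced here; its sign is not, and
the package documents rather than hides this. With `beta = 0.1` the
least-squares slope of breath-mean `P_mus` over t ∈ [30, 150] s is below
10^-3 mmHg s^-1 in the test suite, several hundred times smaller than the
uncorrected drift.

## Variable heart rate

The driver above hard-codes a constant rate through its period. To drive
the model with an arbitrary rate profile HR(t), a phase state `s` with
`ds/dt = HR(t)/60` counts elapsed cardiac cycles; the wrapped phase
`s_w = s mod 1` replaces normalised time inside a unit-period driver
`e(s_w) = A_hat exp(-B_hat (s_w - C_hat)^2)`, `C_hat = 0.5`. For constant
rate `h` the two formulations coincide exactly under
`B = B_hat (h/60)^2`; the tests hold this to 10^-12 pointwise and verify
that full simulated trajectories in the two modes converge to each other
as tolerances tighten. The phase is integrated as an ODE state rather
than by quadrature so HR(t) can be any callable — a constant, the
demonstration ramp `80 + 20 tanh(0.3 (t - 20))` (60 to 100 min^-1), or an
interpolated bedside-monitor trace (`hr_sampled()`: piecewise linear,
constant extrapolation — the simplest continuous choice that does not
invent smoothness the data does not have).

One deliberate simplification inherited from the driver's single-pulse
form: the fraction of the cycle spent in systole does not shorten as the
rate rises, which real hearts do. The width parameter is exposed should a
rate-dependent reshaping ever be wanted.

## Parameters, units and presets

All quantities are expressed in seconds, litres and mmHg; heart rate
alone in min^-1. Four presets ship verbatim from the published tables:
`smith_noninertial` (V_tot 5.5 l), `smith_inertial` (stressed volume
1.5 l, unstressed volumes zeroed — the source's 4 l of dead space is
deliberately dropped by that parametrisation), `jallon` (non-inertial
loop + respiratory model, HR 80), and `jallon_bracketed` (the
reduced-septal-stiffness alternative published alongside: E_es,spt 3750,
lambda_spt 35, E_vc 2, HR 54; kept for reference, used by no headline
result). Two quantities the tables do not provide required a choice:

* the Lienard rate constant `alpha` defaults to 1 s^-1, which makes the
  oscillator equations dimensionally consistent and reproduces the ~5 s
  breath period of the published waveforms; it is exposed in
  `respiratory_params()`;
* the initial alveolar volume defaults to the airflow equilibrium at the
  constant pleural pressure, `V_alv(0) = -P_pl/E_alv` = 4/3.678 ≈ 1.09 l;
  it is exposed in `initial_conditions()`. Long-run behaviour is
  insensitive to it (only the transient changes).

## Numerical design

* **Integrator.** An embedded Dormand–Prince 4(5) pair with the standard
  fourth-order continuous extension and proportional step control
  (safety 0.9, growth clamped to [0.2, 5]), implemented in
  `R/integrator.R`. The valve laws switch derivative branches pointwise
  with no event localisation, so the error controller must reject and
  shrink steps that straddle a closure until the overshoot of the frozen
  flow state sits at the tolerance level; the suite asserts this both on
  a minimal kink problem and on the full model (every valve flow above
  −10^-4 l s^-1 over 60 s at the default tolerances, and the overshoot
  scaling roughly linearly with the absolute tolerance). Accuracy on
  smooth problems is cross-checked against analytic solutions and an
  independent multistep solver.
* **Tolerances.** Defaults `atol = 10^-7`, `rtol = 10^-4`. The absolute
  tolerance sets the spurious-backflow floor of the inertial valves; the
  relative tolerance at its default resolves the dense output around
  valve closures (halving it moves a settled aortic beat by well under
  0.1 mmHg RMS). Output grid `grid_dt = 0.01` s resolves the driver pulse
  without constraining solver steps; step budget 65 536.
* **Septum solve.** Newton tolerance `|f| <= 10^-9` mmHg (near the double
  precision floor given septal stiffness ~5×10^4 mmHg l^-1), iteration
  cap 20, warm start from the previous evaluation. Along a trajectory the
  solve typically converges in ≤ 3 iterations (mean ≈ 2.2); immediately
  at valve-event discontinuities the stale warm start can cost one more.
  If Newton fails (wild trial states proposed by the adaptive stepper), a
  geometrically grown bracket plus bisection recovers the root; if even
  the residual is non-finite, the right-hand side returns NaN and the
  step controller rejects and shrinks the step. The warm start is
  re-seeded from the closed-form linearised solution whenever it has gone
  stale.
* **Initial flows (inertial mode).** Zero-inertia values
  `max((P_up - P_down)/R, 0)` at the initial pressures, satisfying the
  valve law's requirement of non-negative initial flow.
* **Beats and breaths.** Constant-rate beats are delimited analytically
  at period multiples (no threshold choices); variable-rate beats at
  integer crossings of the phase state, located by linear interpolation.
  Breaths are delimited by upward zero crossings of the Lienard pattern;
  the drift statistic is the ordinary least-squares slope of per-breath
  mean muscle pressure against breath mid-time. A beat is labelled
  inspiratory if the alveolar airflow is positive at its start — the
  model offers no sharper operational definition.

## Problem sizes used by the bundled checks

The test suite and acceptance script simulate 60 s of the two Smith
variants (constant and tanh-ramp heart rate) and 150 s of the two Jallon
variants at the default tolerances; shorter horizons (2–20 s) serve the
equivalence, sensitivity and I/O checks. These lengths hold every
asserted contract (conservation to 10^-5 l, backflow floor, drift
statistics over t ∈ [30, 150] s) while keeping a full run of the suite in
the low minutes on one core.

## What the tests do and do not show

The synthetic heart-rate generator produces constant, ramp and bounded
random-walk profiles — enough to exercise phase warping, interpolation and
extrapolation, but not real bedside telemetry: no missed beats, sensor
dropouts, or rhythm disturbances. The model itself omits baroreflex and
autonomic control, pressure-wave reflection and rate-dependent systolic
fraction; consistent with that, the simulated central systolic pressure
rises markedly with heart rate, where pacemaker studies in humans see
mainly a diastolic rise. Passing tests certify the implementation against
the model's own contracts and published parameter tables, not the model
against patients.
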