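# cvrsim

Coupled cardiovascular–respiratory simulation with variable heart rate, in R.

`cvrsim` is for physiological modellers and clinical-data researchers who
need a minimal but complete lumped-parameter (zero-dimensional) model of the
human circulation that can be driven by *measured, time-varying* vital
signs — in particular an arbitrary heart-rate profile — and run stably for
clinically relevant durations (minutes, not a handful of settled beats).

## The model

Six compartments in a closed loop (pulmonary artery and vein, left
ventricle, aorta, vena cava, right ventricle), connected by valves and
resistances, with ventricular interaction through the septum and
pericardium. Each ventricular wall is a time-varying elastance

    P_m(V, t) = e(t) · E_es(V − V_d)  +  (1 − e(t)) · P_0 (e^{λ(V − V_0)} − 1)

driven by a Gaussian activation pulse `e(t) ∈ [0, 1]` per cardiac cycle.
The septum volume solves the nonlinear balance
`P_lvf(V_lv − V_spt) − P_rvf(V_rv + V_spt) = P_spt(V_spt)` (Newton with
analytic derivative; a closed-form linearised alternative is provided).
Valves are either simple check valves or inertial
('open on pressure, close on flow') with flow states.

Three extensions make long, data-driven runs possible:

* **Heart–lung coupling** — a Liènard-oscillator respiratory pattern
  generator drives respiratory muscle pressure and passive lung/chest-wall
  mechanics; the resulting pleural pressure loads the heart and pulmonary
  vessels, reproducing respiratory modulation of the stroke volumes.
* **Stabilization** — integral feedback on the muscle pressure
  (`dP_mus/dt = λ y + μ − β P_mus`, `β = 0.1 s⁻¹`) removes the slow drift
  that otherwise accumulates because the oscillator's cycle mean does not
  exactly balance the offset `μ`.
* **Variable heart rate** — a phase state `ds/dt = HR(t)/60` counts cardiac
  cycles and a unit-period driver is evaluated on the wrapped phase
  `s mod 1`, so `HR(t)` can be any function of time: a constant, a ramp, or
  an interpolated patient trace. For constant rate `h` this reduces exactly
  to the classic driver under `B = B̂ (h/60)²`.

Parameter presets are transcribed verbatim from the published tables
(`smith_noninertial`, `smith_inertial`, `jallon`, `jallon_bracketed`), in
consistent units of seconds, litres and mmHg.

## Worked example: a heart-rate ramp on the inertial model

```r
library(cvrsim)

bundle <- cvr_preset("smith_inertial")
sim <- simulate_cvs(bundle, t_end = 30, hr_profile = hr_tanh_ramp())
sim
#> <cvr_sim> smith_inertial
#>   30 s at dt = 0.01 s (3001 samples); valves inertial; septum nonlinear; respiration none; HR variable
#>   conservation error 4.88e-15 l; min valve flow -0.0011 l/s

beats <- extract_beats(sim)
beats[c(1, 2, 35, 36), c("beat", "t_start", "t_end", "SV_lv",
                         "P_ao_sys", "P_ao_dia", "hr_mean")]
#> # A tibble: 4 × 7
#>    beat t_start  t_end  SV_lv P_ao_sys P_ao_dia hr_mean
#>   <int>   <dbl>  <dbl>  <dbl>    <dbl>    <dbl>   <dbl>
#> 1     1   0      1.000 0.0712     114.     73.2    60.0
#> 2     2   1.000  2.00  0.0733     109.     67.0    60.0
#> 3    35  28.4   29.0   0.0636     136.     98.0    99.8
#> 4    36  29.0   29.6   0.0636     136.     97.9    99.8
```

The heart rate follows the smooth ramp `HR(t) = 80 + 20 tanh(0.3 (t − 20))`
from 60 up to 100 min⁻¹. As the rate rises, stroke volume falls slightly
while systolic and especially diastolic aortic pressure climb
(73 → 98 mmHg diastolic here) — the expected behaviour of a model without
wave reflection or baroreflex. Total blood volume is conserved to rounding
(5 × 10⁻¹⁵ l over 30 s), and the small negative valve flows inherent to the
inertial valve law stay at the solver-tolerance floor.

Other entry points:

```r
glance(sim)                      # one-row run summary (solver diagnostics)
tidy(sim, c("P_ao", "V_lv"))     # long-format signals for plotting
autoplot(sim)                    # waveform panels
plot_pv_loop(sim, "lv")          # ventricular pressure-volume loop

jl <- simulate_cvs(cvr_preset("jallon"), t_end = 150)   # stabilized heart-lung
extract_breaths(jl)              # per-breath metrics
drift_statistic(jl, t_min = 30)  # OLS drift of breath-mean P_mus
```

A thin command-line wrapper ships in `inst/cli/cvrsim`
(`cvrsim run --preset jallon --t-end 60 --out run1`,
`cvrsim fixtures --kind random_walk --seed 7 --out hr.csv`).

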