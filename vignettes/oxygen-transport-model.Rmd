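---
title: "Compartmental oxygen transport during obstructive sleep apnea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental oxygen transport during obstructive sleep apnea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`apneaox` simulates how oxygen moves from breathed air into the blood and on
to the tissues, driven by a time-dependent alveolar-volume input $V_A(t)$.
Four stages are coupled in series:

1. **Alveolar gas.** The alveoli are one well-mixed compartment. During
   inspiration ($dV_A/dt > 0$) fresh humidified air enters at the inspired
   partial pressure $P_I = y_{O_2}(P_B - P_{H_2O})$ and oxygen leaves across
   the alveolar–capillary membrane:
   $$V_A \frac{dP_A}{dt} = \frac{dV_A}{dt}(P_I - P_A)
     - k_l\,(C_A - \bar C_c)\,R\,T,$$
   with $C_A = \beta_p P_A$ the dissolved oxygen at the membrane,
   $\bar C_c$ the spatial average of dissolved oxygen along the pulmonary
   capillary, and $k_l = D_{L,O_2}/\beta_p$ a volumetric conductance (L/s).
   During expiration only the membrane term remains. The two regimes agree
   at $dV_A/dt = 0$; the solver uses the expiration form there (a purely
   cosmetic tie-break).

2. **Pulmonary capillary uptake.** Blood crosses the capillary compartment
   as a FIFO queue of control volumes ("parcels") of fixed blood volume
   $\Delta V = V_{pc}/N$, each obeying
   $$\Delta V \frac{dC_T}{dt} = k_{pc}\,(C_A - C_d), \qquad
     k_{pc} = k_l\,\frac{\Delta z}{L_c} = \frac{k_l}{N},$$
   and advected with the blood velocity $Q/A_{eff}$. Because the parcel
   conductances sum exactly to $k_l$, the summed parcel uptake equals the
   alveolar-side loss identically: oxygen is conserved across the membrane
   by construction, not within a discretization tolerance. A Lagrangian
   queue rather than an Eulerian grid eliminates numerical diffusion along
   the compartment; $\Delta z$ is the parcel length ($L_c/N$).

3. **Hemoglobin chemistry.** Total blood oxygen splits as
   $C_T = C_d + 4\,C_{Hb}\,S(P)$ with $P = C_d/\beta_p$ and the
   dissociation-curve fit $S(P) = \left[1 + 23400/(P^3 + 150P)\right]^{-1}$
   (constants fixed: they define the fit). Only the dissolved component
   drives transmembrane transfer and tissue exposure. The inverse map
   $C_T \to C_d$ is a safeguarded Newton iteration on the strictly
   increasing residual, bracketed on $[0, C_T]$, absolute tolerance
   $10^{-12}$ mol/L; monotonicity makes the root unique, and a plain
   bisection oracle in the test suite pins the solver to $10^{-8}$.

4. **Systemic circulation.** All tissue consumption happens in one systemic
   compartment at the basal rate $MR_{O_2}$: a parcel that enters with total
   concentration $C$ and spends transit time $\tau$ (defined by
   $\int Q\,dt = V_{sys}$, so time-varying flow is handled by a volume exit
   criterion) leaves with $C - MR_{O_2}\tau/V_{sys}$ — the Fick principle
   when flow is constant. Conducting arteries and veins are not modelled:
   concentrations are equated across them (an optional arteriolar leak
   fraction scales the arterial side), so the systemic transit is the only
   systemic delay. Consumption can never drive a concentration negative;
   clamping is counted and reported, since it signals unphysiological
   parameters.

Cardiac output is $Q = \mathrm{HR}\times\mathrm{SV}/60$ from a constant or
recorded heart rate; pulmonary flow equals cardiac output (series
circulation, no shunt).

## Parameters and calibration

Defaults describe a resting adult and are all overridable through
`oxy_params()` / `load_params()`:

| parameter | default | unit | origin |
|---|---|---|---|
| $D_{L,O_2}$ | 21 | mL O$_2$ min$^{-1}$ mmHg$^{-1}$ | physiologic resting diffusing capacity; converted at STPD, 22,400 mL/mol |
| $\beta_p$ | 1.4 | µmol L$^{-1}$ mmHg$^{-1}$ | plasma/membrane O$_2$ solubility |
| $C_{Hb}$ | 2.3 | mmol/L | ~15 g/dL hemoglobin |
| $MR_{O_2}$ | $1.83\times10^{-4}$ | mol/s | calibrated, see below (247 mL O$_2$/min STPD) |
| HR × SV | 75 × 0.07 | bpm × L | calibrated: CO 5.25 L/min |
| $V_{pc}$ | 0.07 | L | pulmonary capillary blood volume |
| $V_{sys}$ | 5.0 | L | systemic transit volume, see below |
| $P_B$, $P_{H_2O}$, $y_{O_2}$, $T$ | 760, 47, 0.21, 310 | mmHg, mmHg, –, K | standard conditions |

Two defaults are calibrated rather than transcribed, and the calibration is
deliberate and minimal:

* **Metabolic rate.** At cyclic steady state the fresh-gas oxygen influx
  must equal consumption, which fixes
  $MR_{O_2} = \dot V_A (P_I - \bar P_A)/(RT)$. Requiring the textbook
  resting alveolar pressure $\bar P_A \approx 99$ mmHg at the reference
  breathing pattern ($V_T = 0.5$ L, $V_D = 0.15$ L, 12 breaths/min) gives
  $1.83\times10^{-4}$ mol/s — 247 mL/min, the textbook resting consumption.
* **Cardiac output.** The Fick relation
  $Q\,(C_{sa,T} - C_{sv,T}) = MR_{O_2}$ together with the resting arterial
  and venous operating points (139 µM and 57 µM dissolved; saturations
  0.977 and 0.76) fixes $Q = 0.0875$ L/s.
* **Systemic volume.** The model lumps every systemic vessel into the
  transit compartment, so $V_{sys}$ plays the role of the whole circulating
  blood volume (5 L), not of the anatomical capillary bed (~0.3 L). With
  0.3 L the systemic side holds essentially no oxygen store: a single
  apnea crashes the arterial saturation within seconds and recovery is
  nearly instantaneous, which contradicts the minutes-scale desaturation
  and recovery dynamics that sleep studies show. 5 L restores the store
  the real circulation provides.

## Numerical scheme

Explicit time stepping with fixed step $dt$ (default 0.005 s), in the order
capillary update → alveolar update → systemic transit, with each stage
using the previous stage's current value (explicit coupling). The advection
constraint $Q\,dt \le \Delta V$ (at most one parcel per step) is checked
before a run and produces an instructive error. The per-parcel uptake uses
an exponential (locally linearized) update: with the local slope
$m = dC_d/dC_T$, the relaxation is integrated exactly over the step. That
makes the hemoglobin-free case match the closed-form exponential to
rounding error and keeps the scheme stable at step sizes where plain Euler
is already marginal (the parcel relaxation rate $k_l/V_{pc}$ is about
160 s$^{-1}$ at the defaults). $N = 40$ parcels resolve the capillary;
doubling $N$ or halving $dt$ moves the steady outputs by less than
0.5% / 0.2% (asserted in the acceptance suite).

Runs begin from the steady state implied by $P_A = 99$ mmHg (all
compartments at the corresponding arterial value, the systemic queue
pre-filled with staggered entry times) followed by a 360-s stabilization
period of event-free breathing before the analyzed pattern starts. Any
initialization that reaches the same cyclic steady state is equivalent;
this one settles well inside the stabilization window.

## Breathing patterns and events

The normal pattern is a sinusoid at breathing rate $b_r$ with peak-to-trough
amplitude $V_{vent} = V_T - V_D$, starting each cycle at end-expiration
($V_A = V_{End}$), inspiration and expiration of equal duration. Apneas
hold $V_A$ at $V_{End}$ (zero airflow); hypopneas scale the oscillation
amplitude by their airflow fraction (applied to $V_{vent}$, since the model
input is alveolar volume); hyperventilation epochs override $V_T$ and/or
$b_r$. Every segment restarts at end-expiration phase, which keeps the
trace continuous provided event boundaries fall at end-expiration; the
bundled scenarios are aligned that way and a misaligned boundary raises a
warning rather than silently jumping. Event durations that are whole
numbers of breathing cycles splice exactly.

AHI arithmetic is deliberately plain: scored events per hour of analyzed
breathing. The clinical filters are explicit arguments — apneas need 10 s,
hypopneas additionally a 4% arterial desaturation, which is evaluated
post-simulation (`score_events()`) because it depends on the model output,
not on the input annotation.

## Patient signal pipeline

The nasal-pressure pathway mirrors clinical practice: annotations (apnea,
hypopnea, RERA, wake) are inputs, not detected. Choices where practice
varies:

* **Ideal tidal volume**: 7 mL per kg of Devine ideal body weight,
  config-overridable.
* **FRC by BMI class**: 3.0 / 2.6 / 2.1 L for normal / overweight / obese,
  configuration values (published averages for subjects assessed for
  sleep-disordered breathing), used as $V_{End}$.
* **Conductance fit**: laminar (linear) pressure–flow relation; the mean
  per-breath peak of the normalized pressure in the clinician-marked
  normal segment is equated with the peak inspiratory flow
  $\pi V_{vent} b_r/60$ of the ideal pattern at the breathing rate
  estimated from upward zero crossings.
* **Integrator drift**: after integrating flow to volume, a rolling
  *minimum* over the normalization window — the running end-expiration
  level — is re-anchored to $V_{End}$. Anchoring the trough rather than
  the mean preserves the tidal excursion; anchoring the mean would shift
  the whole trace by half the tidal volume.

The synthetic generator inverts this pipeline (volume → flow → pressure),
adding Gaussian sensor noise and a slow sinusoidal baseline wander (default
period 600 s, amplitude comparable to the breathing signal). The drift is
deliberately slow relative to the 50–70 s normalization window: that is the
regime the moving-average normalization presumes, and baseline wander in
recordings is minutes-scale (thermal/positional). What the generator does
*not* emulate: obstructive pressure swings against a closed airway, flow
limitation waveshapes, mouth breathing, or sensor dropout — so a passing
round-trip (conductance within 5%, volume within 3% RMS) validates the
plumbing, not robustness to those artifacts.

## Burden scoring

The hypoxia burden of an interval is the signed, time-normalized area
between the wakefulness mean of the arterial dissolved oxygen and the
trace. Signed (overshoot subtracts) rather than clipped, because then
scoring wakefulness itself gives approximately zero, which is the natural
zero point of the scale; `clip_deficit = TRUE` provides the one-sided
variant for sensitivity analysis. The hypoxia-period score restricts to
samples below mean − 1 SD with no dwell-time hysteresis (per-sample
threshold crossing), and divides by time spent below. Trapezoidal
quadrature throughout; interval statistics use the standard one-sample
t-test on interval-minus-overall averages.

## Problem sizes

The bundled validation runs use $dt = 0.005$ s, 40 parcels, 360 s
stabilization plus 120–600 s of analyzed breathing (roughly $10^5$–$2\times
10^5$ steps, seconds to tens of seconds each on one core). These sizes were
chosen so the refinement checks above sit comfortably inside their bounds.

## Known limitations

* **No CO$_2$ or ventilatory control.** Breathing is an input; there is no
  chemoreflex loop, so post-event hyperventilation must be specified, not
  predicted.
* **No pulmonary shunt or regional heterogeneity**; no arteriolar loss by
  default (the leak fraction hook exists).
* **Store-limited desaturation depth.** With the calibrated resting
  parameters, the oxygen available above a given arterial level is fixed by
  the alveolar store $V_{End}\,\Delta P_A/(RT)$ plus the circulating blood
  deficit. A 40-s apnea consumes ~7.3 mmol while the stores above
  $S_{sa} = 0.93$ hold ~5.5 mmol, so the model necessarily desaturates to
  about 0.85 in that scenario, and recovers in roughly half the time some
  published simulations of comparable scenarios report. Matching both the
  resting operating point and shallower event dynamics simultaneously is
  not possible inside this model structure; the resting calibration was
  kept because every default is traceable to it.
* **Pulse oximetry is not modelled**: $S_{sa}$ is arterial saturation at
  the capillary outlet, not a peripheral SpO$_2$ estimate with sensor lag.

```{r, eval = FALSE}
library(apneaox)
sim <- simulate_oxygen(breathing_pattern(load_scenario("fig1_normal")),
                       oxy_params())
summary(sim)
oxygen_metrics(sim)
```
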