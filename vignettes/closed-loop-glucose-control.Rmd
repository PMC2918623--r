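---
title: "Closed-loop glucose control in silico: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop glucose control in silico: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiisim)
```

`aiisim` is an in-silico testbed for an automatic insulin infusion system
intended for hospitalized type-1 diabetic patients: a subcutaneous
continuous glucose sensor drives a proportional-derivative (PD) insulin
controller and an emergency dextrose rescue, actuated through two
quantized clinical infusion pumps, all wrapped around a compartmental
virtual patient. This vignette describes each model, the assumptions
behind it, how the free constants were calibrated, and what the
simulations can and cannot say about real patients.

## The virtual patient

The patient is a single-extracellular-compartment glucose model with
plasma and "active" insulin pools, in the tradition of compartmental
glucose-metabolism models used for insulin-therapy simulation. The
patient secretes no endogenous insulin; everything arrives through the
intravenous line. State variables are glycemia $G$ (mg/dL), plasma
insulin $I$ (mIU/L), active insulin $I_a$ (mIU/L), gut glucose mass
$G_{gut}$ (mg), and two bolus-insulin compartments.

Glycemia obeys a mass balance over the glucose distribution space
$V_g$ (1.8 dL/kg):

$$\frac{dG}{dt} = G_{in}
  + \frac{NHGB - G_{ren} + 60\,IV_{glc}}{V_g}
  - \frac{G_{out} \cdot w}{V_g}$$

with $G_{in}$ the systemic appearance from the gut (mg/dL/h), $NHGB$
the net hepatic glucose balance (mg/h), $G_{ren}$ renal excretion
(mg/h), $IV_{glc}$ intravenous glucose (mg/min) and $G_{out}$ tissue
utilization (mg/kg/h) for body weight $w$.

**Gut.** Oral carbohydrate empties from the stomach along a
trapezoidal ramp–plateau–ramp profile whose area equals the ingested
load; complex-carbohydrate meals empty at half the plateau rate of
pure glucose (`meal_slowdown = 0.5`), which is the only difference
between the "mild" and "moderate" challenges. Absorption from the gut
into blood is saturating (Michaelis form, $V_{max}$ = 1200 mg/min,
$K_m$ = 15 g), and lossless: every milligram emptied is eventually
absorbed, a property the test suite checks to 0.1%.

**Utilization.** $G_{out}$ is the sum of an insulin-independent term
(central nervous system and red cells, 86 mg/kg/h at the reference
glycemia) and an insulin-dependent term linear in active insulin with
slope $c \cdot S_p$, $c = 0.045$ mg·min⁻¹·mIU⁻¹·L. Both are modulated
by a Michaelis factor in glucose normalized to 1 at 100 mg/dL
($K_m$ = 180 mg/dL). $S_p$ (peripheral sensitivity) defaults to 1.0:
with the fixed $c$ above, halving peripheral action makes the system
too sluggish to reproduce the reference device's settling times, so
the reference patient is modelled as peripherally insulin-sensitive
while hepatic sensitivity $S_h$ (default 0.5) carries the
between-patient variation, as in the challenge tables.

**Liver.** NHGB — production minus uptake — is a monotone
piecewise-linear table in *effective insulin* $S_h I$, from
+180 mg/kg/h at zero insulin down to −130 mg/kg/h under strong
hyperinsulinemia, plus a linear glucose term (−2 mg/kg/h per mg/dL
above 100) with its own bounds. Below 85 mg/dL a counter-regulatory
floor overrides insulin suppression,
$NHGB \ge 16\,(85 - G) - 1.5\,S_h I$ mg/kg/h: hepatic glucose output
defends hypoglycemia, and that defense is blunted by circulating
insulin. The table knot at 10 mIU/L (134.128 mg/kg/h) is not arbitrary
— it is solved by `nhgb_basal_value()` so that the closed loop's fixed
point is exactly 100 mg/dL while the insulin line runs at its 1.0 IU/h
keep-vein-open rate (see *Calibration*).

**Insulin kinetics.** Plasma insulin is eliminated first-order
($k_e$ = 0.12 min⁻¹, $V_I$ = 0.1065 L/kg), so a constant infusion $R$
settles at $I_\infty = R/(k_e V_I)$ — 18.6 μIU/mL at the basal
1.0 IU/h in a 70-kg patient. The active pool relaxes toward plasma
insulin at 0.25 min⁻¹; its driving insulin saturates at 250 mIU/L
(receptor-level saturation), a cap above any steady state the pumps
can produce, so it matters only for the spike of an IV insulin bolus.
IV boluses follow a two-compartment model (central volume 3.0 L at
70 kg, $k_{12}$ = 0.02, $k_{21}$ = 0.05, $k_{el}$ = 0.25 min⁻¹); a
10-IU bolus peaks at dose/$V_1 \approx$ 3330 μIU/mL.

## The sensor

The subcutaneous amperometric sensor is a first-order lag with gain:

$$\frac{dS}{dt} = \frac{\alpha\,G(t - T_D) - S}{\tau}$$

with $\alpha$ = 0.23 nA per mg/dL, $\tau$ = 5.77 min and transport lag
$T_D$ = 0 (a ring buffer makes nonzero lags testable). After a step in
glycemia the signal reaches 63% of its equilibrium change at
$t = \tau$. The current is sampled every 10 s with additive white
Gaussian noise (mean 0, variance 100 nA² per raw sample — the variance
is interpreted on the current, not on glucose); each block of 30
samples is averaged, converted through $\alpha$ and clamped to
40–400 mg/dL, yielding 288 readings per day. Averaging 30 independent
samples divides the noise variance by 30, leaving a per-reading
standard deviation of about 1.8 nA ≈ 8 mg/dL — comparable to a
commercial CGM during euglycemia.

## The controller

Once per reading the controller shifts its three-reading history
($G_0, G_5, G_{10}$) and computes

$$A = 0.3\,G_0 - 0.4\,G_5 + 0.1\,G_{10}, \qquad
  DF = \frac{K_2 A}{1 + K_1 A^2}, \qquad
  IR' = \frac{M}{2}\left(1 + \tanh S\,(G_0 + DF - B)\right)$$

with $K_1$ = 1 (mg/dL)⁻², $K_2$ = 10. The $A$ coefficients are the
three-point backward difference of the **per-minute** trend over the
10-minute window; they sum to zero, so constant glycemia gives pure
proportional control, and reversing a trend flips the sign of $A$
exactly. Two considerations fixed this scaling and the rational DF
form during design:

* With the printed $K_1 = 1$, the DF transform peaks at $|A| = 1$
  (DF = ±5 mg/dL) and decays beyond, which is coherent only if $A$ is
  of order 1 for physiological trends — i.e. a per-minute rate
  (meals rise at 1–3 mg/dL/min). A 4-minute-aggregate scaling was
  tried and rejected: it pushes noise-driven $|A|$ far past the peak.
* The decay at large $|A|$ is exactly what a 5-minute-sampled noisy
  sensor needs: inter-reading jumps beyond a few mg/dL/min are almost
  always noise (reading σ ≈ 8 mg/dL), and the rational form
  suppresses them instead of dosing insulin on them. A monotone
  saturating alternative ($K_2 A/\sqrt{1+K_1A^2}$) was evaluated and
  made derivative action noise-dominated.

Below the critical glycemia $G_{crit}$ = 60 mg/dL the emergency logic
cuts insulin to its minimum and enables a proportional dextrose
rescue $GR' = K_G (G_{crit} - G_0)$, $K_G$ = 10 (mL/h)/(mg/dL); at or
above 60 the rescue is off. The insulin command never falls below the
keep-vein-open equivalent (1 IU/h): the venous line must not occlude,
and a type-1 patient must retain enough insulin to avert lipolysis
and ketoacidosis. The 45-minute stretch of minimal infusion seen after
the severe challenge is emergent from the PD law (falling glycemia
drives DF negative and the tanh to its floor); no explicit lockout
timer exists.

## Pumps

Both lines model a volumetric clinical pump: 1.0–500 mL/h in
0.1 mL/h steps (ties round half-up for bit-reproducibility), with a
1.0 mL/h KVO floor on the insulin line and a hard off state on the
dextrose line between emergencies. The insulin solution is 1 IU/mL —
chosen so KVO delivers exactly the 1 IU/h basal — and the rescue fluid
is 50% dextrose (500 mg/mL). All mIU/min ↔ mL/h unit bridging lives at
this boundary.

## Calibration

Free constants were fixed by a scripted, documented procedure, never
per-run:

1. **Maximum rate.** $M$ = 200 mIU/min (12 IU/h), the reference
   system's peak response to the severe challenge.
2. **Basal anchor.** `calibrate_controller_slope()` solves the tanh
   law for the slope that places the KVO command (1 IU/h) at
   103 mg/dL given $B$ = 153 mg/dL, yielding $S$ ≈ 0.024 dL/mg.
   Anchoring slightly *above* the reference glycemia creates a dead
   zone: readings inside the 90–120 band command less than KVO, the
   pump floor delivers the basal 1 IU/h, and the controller simply
   ignores sensor noise until glycemia genuinely leaves the band.
   Anchoring exactly at 100 was tried first and made the loop chase
   noise (σ of true glycemia up to 7 mg/dL with frequent band exits).
3. **Hepatic balance.** `nhgb_basal_value()` returns the NHGB the
   liver must supply at the basal operating point (effective insulin
   9.32 mIU/L for the 70-kg, $S_h$ = 0.5 patient) for glycemia to be
   stationary at 100 mg/dL; the shipped table interpolates it exactly.
4. **Transient shape.** The remaining patient constants (gastric
   emptying $V_{max}$, insulin elimination rate, active-pool rate,
   hepatic glucose slope and hypoglycemia floor) were set so the three
   positive challenges reproduce the published transient envelope —
   peaks near 150/170/180 mg/dL with the published settling behavior
   and no excursion below 60 mg/dL anywhere on the 60–80 kg ×
   $S_h$ 0.3–0.7 grid — while every value stays inside physiological
   ranges. They are ordinary config entries and can be overridden.

## Numerical choices

* Production integrator: classical RK4 at a fixed `dt` = 1/12 min
  (5 s), chosen so the 10-s raw sampling grid falls on every second
  step and the 5-min controller period on every 60th. Halving `dt`
  moves a 24-h trajectory by well under 0.5 mg/dL (tested).
* An independent pure-R explicit-Euler engine
  (`run_closed_loop_reference()`, `dt` = 1/120 min), assembled from
  the exported per-module operations, agrees with the compiled core
  within 0.1 mg/dL over a 6-h meal challenge; this guards against
  transcription drift between the R model functions and the C++ core.
* Sensor noise is pre-drawn in R from one seeded stream per run and
  passed to the integrator, so every run is bit-reproducible from
  `(config, seed)` and the caller's RNG state is never touched.
* Negative state values produced by a step are clipped to zero and
  counted (`n_clipped`); standard scenarios produce none.
* Pump tie-breaking rounds half-up; the 0.1 mL/h lattice is asserted
  property-style over whole simulated days.
* Metrics are computed on true glycemia (the tables describe the
  patient, not the sensor) by a literal scan of the discretized trace;
  an independent brute-force oracle reproduces them exactly on 1000
  random traces. Two settling-time definitions are reported:
  stabilization (time until the trace enters 90–120 mg/dL and stays)
  and first return below 120 mg/dL; figure captions in the source
  literature use the first-return number for the mild meal and the
  stabilization number for the severe bolus, and the package keeps
  both explicit rather than guessing a single convention.

## Study conditions and problem sizes

Simulations follow the reference protocol: a 24-h span with a single
perturbation at minute 600 (hour 10:00), preceded by 10 h of
closed-loop warm-up at the calibrated fixed point. Challenges are
50 g complex carbohydrate (mild), 50 g oral glucose (moderate), 10 g
IV glucose over 30 s (severe) and 10 IU IV regular insulin over 2 s
(negative). Stochastic summaries use medians over 11 seeded
replicates (odd, for unambiguous medians); the sweep covers body
weights 60/70/80 kg × hepatic sensitivities 0.3/0.5/0.7. A full 24-h
run takes ~20 ms in the compiled core, so the complete sweep with
replicates runs in seconds.

```{r example}
res <- run_closed_loop(scn = build_scenario("severe"), seed = 1)
res$metrics
```

## What the generator does and does not emulate

The synthetic patient reproduces: the closed-loop steady state around
100 mg/dL at ~1 IU/h and ~20 μIU/mL; meal, oral-glucose and IV-bolus
excursions with realistic peaks and recovery times; sensor lag, noise,
quantized actuation; and the qualitative dependence of overshoot depth
on hepatic sensitivity and body weight. It does **not** emulate:
circadian or day-to-day insulin-sensitivity variation,
counter-regulatory hormone dynamics beyond the static hepatic floor,
subcutaneous insulin absorption (the device infuses intravenously by
design), sensor calibration drift or dropout, meal announcement, or
multi-challenge days. Passing tests therefore demonstrate the
stability and calibration of the *control algorithm against this
patient model*, not clinical performance; settling times in
particular depend strongly on the unpublished hepatic table and meal
profile, and the moderate challenge settles ~30% slower here than in
the reference report (see the limitations below).

## Known limitations

* The published coefficient set for the trend aggregate and the
  hepatic tables behind NHGB are not public; the shipped defaults are
  calibrated reconstructions. Absolute settling times — the moderate
  challenge especially — inherit that uncertainty even though peaks,
  cadence, basal anchors and all qualitative orderings reproduce.
* A single recovery physiology links the post-challenge undershoot
  behavior of all scenarios: making the moderate meal settle faster
  also shortens the severe bolus's slow sub-90 creep. The shipped
  defaults are the documented compromise.
* The emergency rescue triggers on the *sensed* glycemia; with ~8 min
  of effective sensor delay a sufficiently violent insulin insult
  still produces a transient true-glucose undershoot (as in the
  negative challenge), which no controller gain can remove.
* The 60-kg patients use the same controller tuning as the 70-kg
  reference; the model predicts higher severe-challenge peaks there,
  consistent with the reference tables, but dosing is not
  weight-scaled.
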