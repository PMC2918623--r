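# aiisim

Closed-loop simulation of an automatic insulin infusion system for
hospitalized type-1 diabetic patients.

Tight glycemic control (roughly 80–110 mg/dL) reduces mortality and
morbidity in intensive-care patients, but maintaining it manually
requires hourly capillary sampling and constant nurse attention, with
hypoglycemia (< 60 mg/dL) as the ever-present failure mode. `aiisim`
is an in-silico testbed for the obvious automation: a subcutaneous
continuous glucose sensor feeding a proportional-derivative insulin
controller and an emergency dextrose rescue, actuated through two
quantized clinical infusion pumps, closed around a compartmental
virtual patient. Its purpose is to ask, before any animal or patient is
involved, whether the 5–10-minute delay inherent to subcutaneous
glucose sensing destabilizes the loop — and to measure overshoot,
undershoot and settling behavior under standardized challenges.

The package is aimed at control engineers and physiologists working on
artificial-pancreas algorithms who want a fast, fully reproducible,
scriptable testbed rather than a device prototype.

## The models in brief

* **Virtual patient** — single extracellular glucose compartment:
  `dG/dt = G_in + (NHGB − G_ren + 60·IV_glc)/V_g − G_out·w/V_g`, with
  trapezoidal gastric emptying and saturating gut absorption, a
  monotone net-hepatic-glucose-balance (NHGB) surface in effective
  insulin `Sh·I` and glycemia with a hypoglycemic counter-regulation
  floor, Michaelis-modulated utilization linear in active insulin
  (slope `c·Sp`, `c` = 0.045 mg·min⁻¹·mIU⁻¹·L), threshold-linear renal
  excretion (180 mg/dL), first-order plasma insulin and a lagging
  active-insulin pool, plus a two-compartment model for IV insulin
  boluses. Hepatic sensitivity `Sh` ∈ [0, 1] is the main
  patient-specific parameter.
* **Sensor** — first-order lag `dS/dt = (α·G(t−T_D) − S)/τ` with
  α = 0.23 nA per mg/dL, τ = 5.77 min, additive Gaussian noise
  (variance 100 nA² per 10-s raw sample), 5-minute averaging
  (288 readings/day) and 40–400 mg/dL saturation.
* **Controller** — per reading:
  `A = 0.3·G0 − 0.4·G5 + 0.1·G10` (per-minute trend),
  `DF = K2·A/(1 + K1·A²)` with K1 = 1 (mg/dL)⁻², K2 = 10, and
  `IR' = (M/2)(1 + tanh S(G0 + DF − B))`; below 60 mg/dL insulin
  drops to the keep-vein-open floor and a proportional dextrose rescue
  `GR' = K_G(60 − G0)` engages.
* **Pumps** — 1.0–500 mL/h in 0.1 mL/h steps, half-up tie rounding,
  KVO floor on the insulin line; 1 IU/mL insulin and 50% dextrose.

See the methods vignette
(`vignettes/closed-loop-glucose-control.Rmd`) for assumptions,
calibration and limitations.

## Worked example

A 24-hour run with the severe challenge — 10 g of glucose (20 mL of
50% dextrose) injected intravenously over 30 s at hour 10:00 — for the
reference 70-kg patient with average hepatic sensitivity:

```r
library(aiisim)
res <- run_closed_loop(scn = build_scenario("severe"), seed = 1)
print(res)
#> Closed-loop run: scenario 'severe', 1440 min, seed 1
#> Challenge metrics
#>   overshoot : peak 175.5 mg/dL, duration 17.3 min
#>   undershoot: peak none mg/dL, duration 0.0 min
#>   settling  : Ts 71.5 min (stabilization), 23.5 min (first return)
```

The bolus drives glycemia to a peak of 175.5 mg/dL; it stays above the
140 mg/dL overshoot threshold for 17.3 min, never falls below the
60 mg/dL hypoglycemia line (the keep-vein-open insulin floor plus
hepatic counter-regulation absorb the post-bolus insulin overhang), and
re-enters the 90–120 mg/dL acceptance band for good 71.5 min after the
injection. Before the challenge the loop idles at its calibrated basal
point:

```r
w <- res$series$t >= 120 & res$series$t <= 600
mean(res$series$IR_mLh[w])    # 1.11  IU/h delivered insulin
mean(res$series$I_plasma[w])  # 20.7  uIU/mL plasma insulin
```

`res$series` holds the full per-5-second state trajectory,
`res$trace` one row per controller execution (reading, trend, DF,
commanded and delivered rates, emergency flag), and `res$metrics` the
challenge summary. `build_scenario()` also provides `"mild"` (50 g
complex-carbohydrate meal), `"moderate"` (50 g oral glucose) and
`"negative"` (10 IU IV insulin). `sweep_table()` runs the full body
weight × hepatic sensitivity grid with replicates;
`write_outputs()` exports CSV/JSON; `load_config()` reads YAML/JSON
configurations (see `inst/extdata/example-config.yaml`); and
`inst/scripts/aiis` is a thin command-line front end
(`aiis validate|run|sweep`).

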