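# proton4d

Quasi-continuous 4D dose simulation for synchrotron-based spot-scanning
proton therapy, in R.

When a scanned proton beam treats a target that moves with respiration,
the time structure of the delivery interferes with the time structure
of the motion — the *interplay effect* — and individual pencil-beam
spots land in the wrong place in the target's frame. The result is a
patchwork of hot and cold regions that depends sensitively on the
patient's breathing pattern. `proton4d` is for medical-physics
researchers who want to quantify that degradation and compare
mitigation strategies — amplitude gating, maximum-MU layered
repainting, and their combination — for a synchrotron delivery system,
without a treatment planning system or patient data in the loop.

## What it computes

For a spherical clinical target volume (CTV) with an internal target
volume (ITV) expansion in a homogeneous water phantom:

* **Analytic beam model** — Bragg-curve integral depth dose
  (power-law form with Gaussian range straggling and intrinsic energy
  spread, `R = alpha E^p`), double-Gaussian lateral kernel with beam
  divergence and Moliere-style multiple-scattering growth; compiled
  rasterization onto a 3D dose grid.
* **Plan** — energy layers spanning the ITV, spots on a 2.98-mm
  serpentine lattice, nonnegative least-squares spot weights
  (ridge + within-layer smoothness regularization, minimum-MU pruning)
  delivering a uniform prescription to the ITV.
* **Delivery timing** — discrete-event synchrotron model: energy
  switching/charge refill, spill rate, charge capacity and flat-top
  hold time, scan/step rates, per-delivery spot verification, gate
  on/off latency buffers; spills split when the gate closes mid-spot.
* **4D dose** — every delivery event scored in the target frame at the
  displacement of its temporal midpoint, driven by measured or
  synthetic breathing surrogate traces (Savitzky-Golay smoothed,
  RMS-standardized, baseline-aligned).
* **Metrics** — DVHs, CTV V97%, homogeneity index D5%−D95%, high-dose
  spillage outside the ITV, delivery time; factorial sweeps with
  mean ± SEM across traces.

The delivered monitor units are conserved exactly (bit-level) per spot
through any combination of gating splits and repaint passes.

## Worked example

A scaled study target (1.5-cm CTV + 1-cm ITV margin at 15-cm depth,
100 cGy prescription), one irregular breathing trace, motion orthogonal
to the scan axis, and a 0.3-cm gate combined with 0.005-MU repainting:

```r
library(proton4d)

geo   <- target_geometry(ctv_radius = 1.5, itv_margin = 1)
plan  <- optimize_weights(layout_spots(geo, layer_spacing = 0.45))
plan
#> <proton_plan> 1837 spots in 13 energy layers, pitch 2.98 mm
#>   total 15.223 MU; depths 12.50-17.50 cm

trace <- preprocess_trace(synth_trace("irregular", seed = 11))
trace
#> <breathing_trace> 120.0 s at 40 Hz; range [-0.034, 1.309] cm (preprocessed)

mm <- motion_model(trace, "orthogonal")
cfg <- accumulation_config(spacing = 0.2)
ctv <- sphere_mask(build_dose_grid(geo, cfg), geo$ctv_radius)
itv <- sphere_mask(build_dose_grid(geo, cfg), geo$itv_radius)

# no mitigation
tl0 <- simulate_delivery(plan, mm)
quality_metrics(accumulate(tl0, plan, cfg), ctv, itv, 100, tl0)
#> <plan_quality> V97 = 60.7%, HI = 44.6%, spillage = 5.25 cm3, time = 38.4 s

# 0.3-cm gate + 0.005-MU repainting
tl <- simulate_delivery(plan, mm, gate = 0.3, repaint = 0.005)
quality_metrics(accumulate(tl, plan, cfg), ctv, itv, 100, tl)
#> <plan_quality> V97 = 90.9%, HI = 4.8%, spillage = 0.06 cm3, time = 60.6 s

# static reference
quality_metrics(static_dose(plan, cfg), ctv, itv, 100)
#> <plan_quality> V97 = 100.0%, HI = 2.5%, spillage = 0.18 cm3, time = NA
```

Reading the numbers: the unmitigated delivery collapses target coverage
(V97 from 100% to 61%) and blows the homogeneity index from 2.5% to
45% of prescription; combining a 0.3-cm gate with 0.005-MU repainting
recovers V97 to 91% and near-static homogeneity at the cost of ~58%
more delivery time. `run_sweep()` repeats this over grids of gate
levels × repaint caps × traces × axes and aggregates mean ± SEM across
traces; `write_sweep()`, `write_timeline()`, `write_mhd()` export the
results.

The methods vignette (`vignettes/interplay-simulation.Rmd`) documents
the model equations, every tunable parameter with units and defaults,
the numerical choices, and the known limitations of the scaled study.

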