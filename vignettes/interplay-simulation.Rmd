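---
title: "Simulating interplay and motion mitigation in synchrotron spot-scanning proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interplay and motion mitigation in synchrotron spot-scanning proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proton4d)
```

## The problem

In pencil-beam (spot) scanning, a proton field is delivered as thousands
of small weighted beamlets, layer by layer in energy and spot by spot
within a layer. When the target moves with respiration while the beam
is scanned, individual spots land at the wrong position in the target's
frame — the *interplay effect*. The result is not a blurred dose but a
structured pattern of hot and cold regions that varies strongly from one
breathing pattern to the next.

`proton4d` simulates this process end to end for a spherical target in
a homogeneous water phantom: an analytic single-spot dose model, a
treatment plan with optimized spot weights, a discrete-event model of
synchrotron delivery timing, respiratory surrogate traces, and
DVH-based plan quality metrics. Two mitigation techniques and their
combination can be studied: **amplitude gating** (beam enabled only
while the surrogate is below a threshold) and **maximum-MU layered
repainting** (each layer repeated in passes, every spot delivery capped
at a maximum MU so errors average out across passes).

## Beam model

The integral depth dose (IDD) is an analytic Bragg curve: the power-law
form

$$\hat D(z) \propto (R_0-z)^{1/p-1} + b\,(R_0-z)^{1/p}, \qquad
b = \beta + \gamma\beta p + \varepsilon p/R_0,$$

convolved with a Gaussian range spectrum of width
$\sigma_z = \sqrt{\sigma_{\mathrm{strag}}^2 + \sigma_E^2}$, where
$\sigma_{\mathrm{strag}} = 0.012\,R^{0.935}$ cm is range straggling and
$\sigma_E$ follows from the relative energy spread of the beam through
the range-energy power law $R = \alpha E^p$ (defaults $p = 1.77$,
$\alpha = 0.0022$ cm MeV$^{-p}$). The convolution integral is evaluated
by fixed-order Gauss-Legendre quadrature of a smooth integrand (the
integrable singularity at the monoenergetic endpoint is removed by a
power substitution), so the curve is analytic everywhere — no lookup
tables, no grid artifacts. The model's `range` is defined as the
*Bragg-peak depth*: at construction the monoenergetic endpoint $R_0$ is
solved so that the convolved peak sits at the nominal range (the peak
of the convolved curve otherwise sits about $0.9\sigma_z$ upstream).

The default relative energy spread is 0.8%. Two considerations set it:
it is a realistic synchrotron value, and it puts the composite peak
width $\sigma_z \approx 0.26$ cm at mid-range in a regime where the
default 0.45-cm energy-layer spacing produces a depth-homogeneous
plan (spacing below roughly $2\sigma_z$ leaves no inter-layer ripple
worth correcting). Both parameters are configurable.

Laterally each spot is a double Gaussian,
$(1-w)\,G_2(\sigma_1(z)) + w\,G_2(k\sigma_1(z))$ with defaults
$w = 0.05$, $k = 3$. The primary sigma is the quadrature sum of the
in-air spot size scaled by divergence from a 245-cm source-to-isocenter
distance and a multiple-scattering term growing as a power law
$\sigma_{\mathrm{scat}}(z) = c\,R\,(z/R)^{1.7}$ with $c = 0.0224$
(about 2.2% of range at the full range, a few mm at clinical depths).
The in-air sigma is interpolated from a per-range table and must lie in
the machine envelope of 3-6 mm. None of these shape coefficients are
measured values for a specific nozzle; they are explicit, documented
model inputs.

Absolute dose is set by one calibration: the IDD at the Bragg peak,
450 cGy cm²/MU by default. Together with the prescription it fixes the
scale of optimized spot weights; the default puts a plan's mean spot
weight near 0.008 MU, the regime in which repainting caps between
0.002 and 0.02 MU per delivery are meaningful and a clinical-scale
plan totals on the order of $10^2$ MU.

Rasterization evaluates the kernel analytically at voxel centers
(no sub-voxel integration; a grid-refinement test bounds the effect on
coverage metrics below one percentage point) and truncates it per
lateral axis at $5k\sigma_1$, conserving the per-slice lateral integral
MU·IDD to better than 0.1%. The inner loop is compiled code; each slice
update is two rank-one outer products.

## Plan construction

The study geometry is a spherical CTV with an isotropic ITV expansion
(defaults 3 cm + 1 cm at 15 cm depth; tests and the acceptance study
use a scaled 1.5 cm + 1 cm target). Energy layers span the ITV in
depth, distal to proximal; each layer carries a square lattice of spots
at 2.98-mm pitch covering the ITV cross-section plus a one-sigma
lateral margin, ordered serpentine: rows by increasing $y$, the first
row scanning $+x$, alternating direction, with only a perpendicular
step between rows.

Spot weights minimize
$\|A w - D_{rx}\|^2 + \lambda\|w\|^2 + \mu\, w^\top L w$ subject to
$w \ge 0$, where $A$ is the dose-influence matrix on a coarse
optimization grid inside the ITV (default 3 mm; the evaluation grid is
finer) plus a Fibonacci-sampled shell of points on the ITV surface, and
$L$ is a graph Laplacian over each layer's spot lattice. The ridge
selects a spread solution of the underdetermined system; the Laplacian
selects smooth per-layer fluence, which is what clinical spot-weight
regularization produces — without it the active-set solution
concentrates weight in a sparse subset of spots and every energy layer
becomes individually lumpy, which distorts the motion response.
Defaults ($\lambda$, $\mu$ = 0.01, 0.03 relative to the mean diagonal
of $A^\top A$) were chosen on *static* plan quality: the delivered
static plan reaches ITV V97% ≥ 99% and D5%−D95% ≤ 5% of prescription.
Weights below the minimum deliverable 0.001 MU are pruned and the fit
re-run, so every emitted spot is deliverable. The solver is a clipped
normal-equation active-set iteration written for this package; with
$\lambda = \mu = 0$ and a consistent full-rank system it reproduces
known weights to numerical precision, which the tests exploit as an
oracle.

## Breathing traces

Surrogate traces are two-column text (time s, position cm), loaded and
resampled to a uniform 40 Hz. Standardization applies, in order: a
second-order Savitzky-Golay filter with a 1-s span; a multiplicative
scale putting the RMS amplitude about the mean at $1/(2\sqrt2)$ cm —
the RMS of a sinusoid of 1-cm peak-to-peak amplitude, so traces of
different subjects share a nominal motion magnitude; and a shift
placing the quiescent minimum (the 5th percentile, robust to
single-sample dips) at $y = 0$, the coordinate in which gate thresholds
are defined. RMS is computed after smoothing and before shifting (the
shift cannot change RMS about the mean; the order is fixed for
determinism).

The synthetic generator produces either the idealized
$y(t) = A\sin^4(\pi t/T)$ or an irregular trace: per-cycle amplitudes
and periods drawn from mean-preserving lognormals (default CV 0.15
each), and a baseline random walk (default 0.05 cm per cycle)
interpolated linearly across each cycle so the trace stays continuous.
Defaults $A = 1$ cm peak-to-peak and $T = 5$ s are typical adult
respiration. With all jitter zero the irregular generator reduces
exactly to the $\sin^4$ form. All randomness flows through an explicit
seed. What the generator emulates is the *surrogate*: cycle-to-cycle
variability of amplitude, period, and baseline. What it does not
emulate: drifting breathing frequency spectra, coughs and breath-holds,
imperfect surrogate-target correlation (the target is assumed perfectly
correlated with the marker, moving along a single lateral axis), and
any 3-D composite trajectory. Passing tests therefore show that the
delivery and scoring chain responds correctly to realistic variability,
not that any specific patient outcome is predicted.

Motion is mapped to one axis in the beam's eye view: `parallel` moves
the target along the fast raster scan axis, `orthogonal` along the row
step axis. Deliveries can outlast a recording, so traces tile
periodically by default (configurable to error).

## Delivery timing

The simulator advances an event clock through the plan: per layer, one
combined energy-switch/charge-refill operation (2.3 s, treated as a
single shared operation since the machine merges them); then the
repaint passes in serpentine order, each pass replaying the same spot
order. Per spot: travel from the previous spot as sequential axis moves
(x-distance at 10 m/s plus y-distance at 6 m/s — the conservative
reading; max-of-axes is configurable), 2.5 ms position verification per
delivery event (each repaint pass is a distinct delivery), and a spill
at 0.5 nC/s with 0.1 nC/MU. The ring holds 2 nC; when stored charge is
exhausted, or the 8-s flat-top timer started at refill completion
expires, residual charge is dumped and a refill (2.3 s) is required. A
refill may run concurrently with a gate-off wait, so the flat-top is
fresh when the beam window opens; ungated deliveries are unaffected by
this rule.

Amplitude gating compares the surrogate position against the threshold:
the raw gate is open while $y(t)$ is below it; beam permission lags the
raw signal by the latency buffers — on 200 ms after a raw off→on
transition, off 40 ms after on→off (so the beam still delivers during
the 40-ms off latency). A spill in progress is interruptible: when
permission drops mid-spot, the delivered sub-interval becomes its own
event and the remainder resumes after the next window opens. Every
event is stamped with the target displacement at its *temporal
midpoint*, which is accurate because single deliveries last
milliseconds while breathing periods are seconds. A configurable wall
limit turns a never-opening gate into a diagnostic error rather than an
infinite loop.

Repainting partitions each weight into passes of at most the configured
maximum MU; when the remainder after a pass would fall below the
minimum deliverable MU, the preceding pass absorbs it, exceeding the
cap by less than the minimum. The partition and the per-event ledger
are constructed by cumulative subtraction in plain double arithmetic,
so the left-to-right sum of every spot's delivered events reproduces
the planned weight bit-for-bit (R's `sum()` accumulates in extended
precision and is deliberately avoided in this invariant).

## Dose accumulation and metrics

Dose is scored in the target's frame: each event's kernel is rasterized
at the spot position minus the displacement at its midpoint, so the
static CTV/ITV masks remain valid — equivalent to the moving-target
view under the rigid-target, homogeneous-phantom idealization, which
deliberately isolates interplay from range changes caused by upstream
motion (excluded by design, along with tissue heterogeneity and
deformation). The default scoring grid is 0.75 mm isotropic, covering
the ITV plus a 2-cm margin; events whose kernel support leaves the grid
are clipped, warned about, and ledgered as out-of-grid MU.

Plan quality distills DVHs into: CTV V97% (volume receiving ≥ 97% of
prescription), homogeneity index D5%−D95% as a percentage of
prescription, high-dose spillage (volume outside the ITV at or above
prescription, at voxel centers with a strict ≥ threshold), and total
delivery time. D-quantiles are computed by linear interpolation between
order statistics of the exact voxel doses (conventions differ between
systems; this one is stated and tested against sort-based brute force),
while exported DVH curves are binned at 0.1 cGy for plotting. Sweeps
over gate levels × repaint caps × traces × axes report per-cell metrics
and the mean ± SEM across traces (sample SD over $\sqrt n$), with the
no-mitigation cell appearing exactly once, shared by the gate-only and
repaint-only series.

## Numerical choices

* Gauss-Legendre order 64 for all depth-dose quadratures; peak
  location solved to $10^{-6}$ cm at model construction.
* Repaint partition decisions use a $10^{-9}$ MU tolerance at the
  cap/minimum boundaries; part values themselves are exact cumulative
  differences.
* The active-set weight solver adds a relative jitter of $10^{-12}$ to
  the normal equations for rank safety; pruning/refit loops at most 5
  times.
* Serpentine tie-breaks: rows ordered by increasing $y$, first row
  scans $+x$; repaint passes replay the same order.
* Degenerate configurations are exact aliases: no gating equals a
  threshold above the trace maximum, no repainting equals a cap at the
  maximum weight, zero-amplitude motion equals the static delivery —
  all bit-identical, which the tests assert.

## Scaled study and its limitations

The package's test and acceptance study uses a 1.5-cm CTV (1-cm ITV
margin), a 2-mm scoring grid, and 10 irregular traces at nominal 1-cm
peak-to-peak under fixed seeds — sizes chosen so the whole suite runs
on a desktop in minutes. Two regime differences from a clinical-scale
study follow from that choice and matter when interpreting results:

1. The scaled plan has ~140 spots per layer, so a layer is painted in
   under a second, while a clinical-scale plan takes a few seconds per
   layer. Each scaled layer is therefore quasi-frozen at one breathing
   phase, and no-mitigation degradation is dominated by lateral
   misalignment of whole layers — a mechanism that is symmetric between
   the parallel and orthogonal motion axes. The axis asymmetry expected
   from within-layer row dynamics is real but small at this scale, and
   its sign is not statistically resolved across 10 traces.
2. Under gating, the 2.3-s energy switch spans most of a gate-off
   phase, so successive layers phase-lock to the post-buffer descent of
   successive cycles. The resulting few-percent row-spacing dilution
   sits exactly at the V97 cliff (static CTV doses are a few percent
   above the 97% line), so gate-only coverage for orthogonal motion
   does not reliably improve on no mitigation at this scale, even
   though homogeneity improves by an order of magnitude and combined
   gating + repainting restores both. At clinical scale a layer spans
   entire gate windows, sampling descent, quiescence, and rise, and the
   dilution largely cancels.

Both effects were verified mechanistically (controlled constant-offset,
ramp, and phase-locked traces against an independent analytic dose
oracle), not inferred from the metrics alone. The acceptance script
reports exactly what the scaled study computes; nothing in it is
calibrated against external results.

## A minimal session

```{r example, eval = FALSE}
geo <- target_geometry(ctv_radius = 1.5, itv_margin = 1)
plan <- optimize_weights(layout_spots(geo, layer_spacing = 0.45))
trace <- preprocess_trace(synth_trace("irregular", seed = 11))
timeline <- simulate_delivery(plan, motion_model(trace, "orthogonal"),
                              gate = 0.3, repaint = 0.005)
dose <- accumulate(timeline, plan, accumulation_config(spacing = 0.2))
quality_metrics(dose,
                sphere_mask(dose, geo$ctv_radius),
                sphere_mask(dose, geo$itv_radius),
                geo$prescription, timeline)
```
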