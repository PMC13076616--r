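---
title: "Models and methods: evolving elementary motion detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: evolving elementary motion detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdevolve)
```

## The circuit model

`emdevolve` simulates the smallest circuits that can compute visual motion
direction: a layer of directionally *untuned* presynaptic cells, each with
its own spatiotemporal receptive field (RF), converging onto a single
postsynaptic detector. Direction selectivity (DS) of the detector must
therefore arise from asymmetries in how the inputs filter the stimulus, not
from any directional tuning of the inputs themselves — each presynaptic cell
responds identically to a full-field flash regardless of its spatial RF.

### Stimuli

All stimuli are intensity fields in `[0, 1]` on a square arena (default
800 µm wide, 5 µm pixels, 5 ms frames; background 0, full contrast 1):

* **Moving bars** (`make_moving_bar()`): a bright bar 1 mm high, oriented
  perpendicular to its motion, translating at constant speed. Its temporal
  width is 0.2 s, so its spatial extent along the motion axis is
  `speed × 0.2 s` and every point in the arena is covered for exactly 0.2 s
  at any speed. We interpret the bar's "duration" as this temporal width
  rather than a fixed spatial width because a fixed spatial width would make
  a duration parameter undefined across speeds; a spatial override is
  exposed for users who want the other convention. The canonical protocol
  uses five speeds (0.25, 0.5, 1, 2, 4 mm/s) and 12 equally spaced
  directions. Bars are rendered with hard binary edges (no anti-aliasing),
  consistent with the 0/1 intensity convention; sub-pixel edge effects are
  below the overlap-oracle tolerance.
* **Drifting gratings** (`make_drifting_grating()`): full-field sinusoids at
  100% contrast on a gray (0.5) background, default 1 mm/s, spatial periods
  100–1600 µm/cycle. Gratings carry their own background convention (0.5)
  while bars use 0.
* **1-D contrast noise** (`make_1d_bar_noise()`): 20 µm bars spanning the
  field, each independently 0 or 1 with probability one half, updated every
  20–200 ms; used for space-time RF mapping.
* **Variable-velocity bars** (`make_variable_velocity_bar()`): the bar's
  speed is redrawn every 50 ms from the positive half of a normal
  distribution (SD up to 5 mm/s) so the bar never reverses; used for the
  noise-robustness protocol. The base speed is 1 mm/s — the protocol's
  source does not state it, and 1 mm/s is the canonical probe speed
  everywhere else in the package.

### Presynaptic receptive fields

Each RF component (center, and optionally an antagonistic surround aligned
with the center) is an elliptical 2-D Gaussian. The spatial overlap between
a component and the stimulus at time *t* (`rf_overlap_area()`) is the
pixel-by-pixel stimulus-weighted Gaussian sum, normalized by the component's
full-arena Gaussian sum so that full-field illumination gives exactly 1.
The normalizing denominator is a choice: the source description
("normalized fraction of the stimulated RF area") does not state it, and
per-component normalization makes center and surround commensurate in the
subtraction step. Note that, as defined, the `size` parameters are the
distances at which the profile falls to half maximum (the full width at
half maximum of the profile is twice `size`); we implement the printed
formula verbatim.

Temporal filtering follows a first-order recursion with
readily-releasable-pool (RRP) adaptation:

```
RF_t    = (area_t - RF_{t-1}) * dt / rise + RF_{t-1} * adaptation_{t-1}
adapt_t = max(0, adapt_{t-1} - RF_t * dt / decay)
```

The `decay` constant governs RRP depletion, not the post-stimulus decay of
the response (which is governed by `rise`); the recursion is implemented
exactly as specified even though the conventional reading of "decay time"
differs. Note the adaptation state never recovers within a trial — it is
monotone non-increasing — so each trial starts with a full pool
(`adaptation = 1`). A response delay (0–50 ms, used in kinetic-variant
models) shifts the overlap series before filtering. Center and surround are
filtered independently (the surround is a separate spatiotemporal filter
with its own size and kinetics), then combined as

```
RF_full = w_syn * max(0, RF_center - w_surround * RF_surround)
```

— subtraction, rectification (release cannot be negative), then weighting.

### Short-term plasticity

Depression multiplies release by a pool state that starts at 1, is depleted
multiplicatively by the driven release (`dep_amp` in [0, 1]) and recovers
toward 1 with first-order kinetics (`dep_tau` > 10 ms). The printed form of
this update references the *facilitation* amplitude and time constant inside
the depression recursion and decays the pool toward zero; we treat that as a
cross-referencing slip and implement self-contained depression by default,
keeping the literal recursion available behind `plasticity_params(literal =
TRUE)` for comparison. Facilitation integrates the driven release, decays
with `fac_tau`, is clipped to [0, 1] (the clip is enforced explicitly since
only the admissible range is stated), and multiplies release by
`10^state`, so facilitation can amplify release by at most a factor of ten.

### Spiking afferents

Cortical-variant cells convert the graded trace to spikes: at each step a
uniform draw on [0, 0.3] is compared with the trace. The rule as printed
fires when the draw *exceeds* the trace, i.e. fewer spikes for stronger
drive; we invert the comparator by default (spike when draw < trace) so
that firing increases with drive, which is the premise of the cortical
simulations, and keep the printed comparator behind `literal = TRUE`.

### Postsynaptic back-ends

* **Minimal detector** (`simulate_minimal_detector()`): a weighted linear
  sum of two presynaptic waveforms; no cable, no rectification.
* **Point detector**: the same linear sum over an arbitrary population.
* **Compartmental model** (`simulate_compartmental()`): a passive cable on
  a dendritic tree, solved with an implicit (backward Euler) step on the
  Hines-ordered tree — unconditionally stable, first-order accurate; the
  convergence tests require the peak somatic response to move by less than
  0.5% under dt halving. Passive defaults: specific conductance
  4e-4 S/cm², capacitance 1 µF/cm², rest −60 mV, axial resistivity
  150 Ω·cm; voltage step 0.1 ms. Excitatory reversal 0 mV; the inhibitory
  reversal is not specified by the source and defaults to −70 mV
  (hyperpolarizing-shunting, 10 mV below rest), configurable in
  `build_chassis()`.
* **Spiking soma**: optional Hodgkin–Huxley-style Na⁺/K⁺ conductances at
  the soma only (densities 10,000 and 2,000 pS/µm²) with classic squid
  kinetics shifted to a −60 mV rest; spike count is the number of upward
  0 mV crossings.

Morphologies are procedurally generated *surrogates* (planar radially
branched "ganglion-cell-like" arbors, default 352 segments; apical/basal
"pyramidal-like" arbors, default 69 segments), not reconstructions; SWC
read/write is provided. Synaptic conductance per unit drive (`g_unit`)
defaults to 0.75 nS, calibrated so one maximal synapse depolarizes the
surrogate ganglion-cell soma by about 1 mV; it is exposed in the chassis
because the fitness saturates through `tanh` and is therefore sensitive to
the absolute scale. Retinal wiring places each RF center uniformly in a
300 µm circle over the soma and connects it to the nearest dendritic
segment; cortical wiring covers a wider field (400 µm) and connects to
uniformly random segments.

## The genetic algorithm

Each generation holds 10 models. The best model (by the directional metric)
is kept intact — so best fitness is non-decreasing — and seeds 9 mutated
copies. Every free parameter is multiplied by a draw from `N(1, 0.1)` and
shifted by a uniform draw on ±0.015 *in its native unit* (the additive term
is implemented literally even though units differ across parameters), then
clipped to its bounds. Clipping (rather than reflection or resampling) is
the simplest rule consistent with the stated hard bounds. *Shared*
parameters draw one mutation applied to all four input groups; *independent*
parameters draw per group. Initial values are uniform within the stated
limits (center half-width 10–200 µm, surround half-width > 10 µm, time
constants > 10 ms, delays 0–50 ms, strengths and plasticity factors 0–1,
passive conductance 1e-5–1e-3 S/cm², axial resistivity 50–200 Ω·cm).

Fitness for one speed is `DSI × tanh(max R)`, where `R` is the peak somatic
depolarization above rest (mV, floored at 0) per direction and DSI is the
vector-sum index `Σ R cosθ / Σ R` with θ = 0 the designated preferred
direction. The metric (not the DSI) is averaged over the five stimulation
speeds. Putting millivolts inside `tanh` is a unit choice the source leaves
open; it saturates around 3 mV, rewarding depolarizations of a few
millivolts, which matches the subthreshold focus of the retinal model, and
the scale can be changed through `g_unit`. Minimal models use a single
velocity (1 mm/s) and two opposite directions, and their two cells sit
100 µm apart on the preferred axis — a separation the source does not
state, chosen as the typical spacing of two adjacent input-group centers
within the 300 µm input field. The input groups of the full model are
position quartiles along the preferred axis, the least parametric reading
of "populations arranged sequentially along the preferred motion axis".

`grid_search_minimal()` provides a brute-force optimization oracle on
low-dimensional minimal models; the test suite requires the GA to reach at
least 95% of the exhaustive-grid optimum.

## Analysis

* **DSI** (`dsi()`): `Σ R_θ cos θ / Σ R_θ`, zero when all responses vanish.
  For gratings the response magnitude is the steady-state peak-to-peak
  voltage over the final 30% of the trial (`grating_dsi()`).
* **Kinetic axis** (`hr_metric()`): per-synapse response durations (FWHM of
  the preferred-direction motion response, measured on the largest
  contiguous super-half-maximum interval for multi-peaked responses)
  regressed on position along the preferred axis; narrowing toward the null
  side is the positive (delay-and-compare) direction, and the magnitude is
  `(1 − narrowest/widest)²`.
* **Overlap axes** (`amplitude_metric()`, `alignment_metric()`): traces are
  peak-normalized; the amplitude variant first aligns each trace on its
  peak time (the alignment anchor is unstated in the source; peak-time
  alignment is the least parametric rule) and requires 75% of the
  population above 20% of peak, the alignment variant uses raw timing and a
  25% quorum. The overlap waveform is the population mean at qualifying
  times; the metric is its mean over active times normalized by its own
  peak (the normalization constant is likewise a package choice).
* **Inhibitory axes** (`bl_metrics()`): the excitatory response's area is
  split into exact thirds (sample bins are treated as rectangles so the
  third-points interpolate exactly); the veto metric is the fraction of
  preferred-direction inhibition in the last third-window, its mirror the
  first; tuned inhibition compares per-direction peak inhibitory drives
  (Eq.-style normalized difference, floored at 0), and the pause metric —
  only defined when both timing metrics are below 0.20 — replaces the
  preferred peak with the middle-window peak.
* **Classification** (`classify_primitives()`): excitatory coordinates are
  (kinetic metric, alignment − amplitude); inhibitory coordinates are
  (last-third − first-third, pause − tuned). The source defines the
  pause/tuned-inhibition axis only pictorially; combining the two
  half-axis metrics as a signed difference, with the pause term zero when
  undefined, mirrors the excitatory convention. A primitive is present when
  its coordinate passes 0.20; two present axes make a hybrid.
* **Noise robustness** (`noise_robustness_curve()`): per trial, one
  velocity trajectory presented in the preferred and the null direction
  gives a two-direction DSI; per-level means are normalized to the
  noise-free baseline and summarized by a linear-regression slope
  (`noise_slope()`); model families are compared by ANOVA over per-run
  slopes.
* **Space-time maps** (`spacetime_map()`): ON-phase (white-bar onset)
  triggered averages in 20 ms bins per bar position; the temporal RF is the
  central-position row and the spatial RF the column at the time of maximal
  absolute response. Stored maps are signed (mV); the
  depolarizing-green/hyperpolarizing-red convention applies only in
  `autoplot()`.

## What the generator emulates — and what it does not

The stimulus engine and circuit generator reproduce the *study conditions*:
arena geometry, bar/grating/noise parametrizations, RF parameter ranges,
wiring rules, GA hyperparameters. They do not emulate photoreceptor
adaptation, naturalistic image statistics, synaptic failure, or dendritic
active conductances; passing tests therefore demonstrate properties of the
model class, not of retinal tissue. The surrogate morphologies preserve
segment counts and field size but not the branching statistics of real
reconstructions, so full-model DSI values are comparable only in rank order
and approximate magnitude, not digit-for-digit.

## Numerical choices and problem sizes

Pixel size defaults to 5 µm (at most a quarter of the narrowest RF) and the
reference tests require the fast overlap paths to agree with a dense
rendered sum at half the pixel size within 1%. The stimulus step is 5 ms
(within the stated 1–10 ms envelope); conductances are linearly
interpolated onto the 0.1 ms voltage grid inside the solver. Kinetic
parameters are bounded below by the stimulus step (the recursion requires
`dt < rise, decay`); initialization uses 10 ms as the lower limit and
300 ms as the upper (only the lower limit is stated). Weight bounds are
[0, 2] with uniform [0.2, 1] initialization.

The package's own test campaigns run at reduced scale, chosen once:
8 synapses per population, a 32-segment surrogate arbor, 4 directions ×
1 speed (1 mm/s), 10 µm pixels, 10 ms stimulus frames, 0.4 ms voltage step,
and 10–20 runs of 60–300 generations per scenario (point-detector phenotype
campaigns use 8 cells and 4 directions; noise curves use 50 trials per
level); the minimal-model campaigns run at the canonical conditions (two
cells, two directions, 1 mm/s, 300 generations, 20+ runs).
The reduction preserves the mechanisms (each template still evolves its
characteristic phenotype ordering) while keeping the whole suite within a
desk-scale compute budget; consequences for comparability with the
full-scale numbers are flagged wherever a test asserts only rank order.

## Known limitations

* The adaptation pool never recovers within a trial; stimuli longer than a
  few depletion time constants progressively silence strongly driven cells.
* The minimal weight-asymmetry model has one dominant solution basin — the
  sharply-rising/slowly-decaying, weaker-input-first optimum near DSI 11% —
  plus a weak secondary local optimum with slower kinetics and reversed
  weights (the later input silenced, selectivity from the causal asymmetry
  of the temporal filter on an off-center cell) that a minority of runs
  settle into and do not leave even after 1000 generations. In this
  implementation the secondary branch reaches only a few percent DSI, well
  below half of the optimum; campaign summaries split branches by a
  data-driven two-means clustering of the evolved rise times.
* Backward Euler is first-order; peak voltages carry O(dt) bias (below 1%
  at the default step, verified against closed forms).
* The cortical back-end models spiking afferents as per-step Bernoulli
  events at the stimulus resolution; refractory dynamics and unitary-event
  kinetics are not modeled.
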