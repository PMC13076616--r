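# emdevolve

Simulation and analysis toolkit for **elementary motion detection**: the
smallest neural circuits — a layer of directionally untuned presynaptic
cells converging on one postsynaptic detector — that can compute the
direction of visual motion. The package is written for computational
neuroscientists who want to ask *which receptive-field asymmetries suffice
for direction selectivity*: it generates parametric visual stimuli, drives
populations of center–surround Gaussian receptive fields with short-term
synaptic dynamics, integrates their conductances in linear, passive-cable,
or spiking postsynaptic models, evolves circuit parameters with an elitist
genetic algorithm, and classifies the evolved solutions into computational
primitives (Hassenstein–Reichardt and anti-Hassenstein–Reichardt kinetics,
amplitude and temporal-alignment overlap; Barlow–Levick and
anti-Barlow–Levick inhibition, pause-in-inhibition, tuned inhibition).

## The model in brief

A presynaptic cell's drive to the detector is

```
area_t   = normalized Gaussian-weighted stimulus overlap        (space)
RF_t     = (area_t − RF_{t−1})·Δt/τ_rise + RF_{t−1}·adapt_{t−1} (time)
adapt_t  = max(0, adapt_{t−1} − RF_t·Δt/τ_decay)                (RRP pool)
RF_full  = ω_syn · max(0, RF_center − ω_surround·RF_surround)   (integration)
```

optionally passed through short-term depression (multiplicative pool,
first-order recovery) and facilitation (release × 10^state, state ∈ [0,1]).
Directional tuning of the detector is quantified by the vector-sum index

```
DSI = Σ_θ R_θ cos(θ) / Σ_θ R_θ
```

over the tested motion directions (θ = 0 the preferred direction, R_θ the
peak somatic depolarization), and the genetic algorithm maximizes
`mean over speeds of DSI · tanh(max R_θ)` with a population of 10, one
elite, and multiplicative `N(1, 0.1)` + additive `U(−0.015, 0.015)`
mutations. See the methods vignette
(`vignettes/motion-detection-methods.Rmd`) for every equation, default and
design decision.

## Worked example

Evolve the minimal two-input weight-asymmetry detector (two presynaptic
cells with identical evolvable filters, independent synaptic weights, a
linear detector, one bar speed, two opposite directions):

```r
library(emdevolve)

cfg <- load_preset("weights_minimal", generations = 300, n_runs = 1)
arch <- run_experiment(cfg, seed = 7)
report(arch)
#> Experiment 'weights_minimal': 1 runs x 300 generations (master seed 7)
#>   fitness: 0.1063 +/- NA
#>   mean DSI: 11.05% +/- NA%
#>   per-speed DSI (%): 1: 11.1
#>   run seeds: 172976045

run <- arch$runs[[1]]
glance(run)
#> # A tibble: 1 × 4
#>   generations best_fitness mean_dsi      seed
#>         <int>        <dbl>    <dbl>     <int>
#> 1         300        0.106    0.111 172976045
```

The evolved solution reaches a direction selectivity index of about 11%:
the weaker input is recruited first in the preferred direction, and the
slowly decaying response of the first cell summates with the stronger,
later input — the circuit's entire selectivity comes from the weight
asymmetry, since both filters are identical. `tidy(run)` returns the
per-generation fitness trajectory and `autoplot(run)` plots it;
`directional_tuning(run)` tabulates the per-direction responses.

Other presets (`preset_names()`) reproduce the full circuit scenarios —
kinetic, receptive-field size, orientation, surround, synaptic-weight and
inhibitory variants on a surrogate multicompartment ganglion-cell model, a
cortical spiking variant, velocity-noise robustness and 1-D-noise
receptive-field mapping.

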