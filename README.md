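# cannstd

Simulation and analysis of **continuous attractor neural networks
(CANNs) with short-term synaptic depression (STD)**, and of the
temporally modulated *population spikes* that let such networks resolve
overlapping stimuli — e.g. two transparently superimposed motion
directions — below the tuning width of the neurons.

The package is for computational neuroscientists who want to reproduce,
probe or extend this mechanism: a fast rate-based ring-network
integrator, the fluctuating multi-component stimulus model, and the full
population-spike readout (thresholded peak statistics, histograms and
bimodality tests, resolution curves, regime classification, phase
diagrams, bias-conditioned maps), plus no-STD, local-inhibition and
purely feedforward control variants.

## Model

On a periodic ring of `N = 80` preferred directions spanning 360°, the
rescaled current field ũ(x, t) and neurotransmitter fraction p(x, t)
follow

    τ_s dũ_i/dt = −ũ_i + Ĩ_i + Σ_j W_ij p_j r̃_j
    τ_d dp_i/dt = −p_i + 1 − β̃ p_i r̃_i
    r̃_i = Θ(ũ_i) ũ_i² / B,   B = 1 + k̃/(8√(2π)a) Σ_j dx ũ_j²

with Gaussian recurrent weights of range `a` (tuning width = 2a = 96°),
divisive global inhibition k̃, depression strength β̃ and recovery time
τ_d = 50 τ_s.  The external input is a sum of Gaussian components whose
amplitudes fluctuate independently every 50 τ_s and whose combined peak
is held at a fixed strength Ã.  For moderate Ã, STD makes the response a
train of localized population spikes; their thresholded peak positions
— not the time-averaged rate — carry the stimulus separation.

## Worked example

Two stimuli 72° apart (0.75 tuning widths — well below what a
time-averaged tuning curve can separate):

```r
library(cannstd)
params <- cann_params()          # k = 0.5, beta = 0.24, tuning width 96 deg
stim   <- cann_stimulus(centers = deg_to_rad(c(-36, 36)), A = 0.8, sigma = 0.3)
sim    <- simulate_cann(params, stim, duration = 20000, seed = 42)
print(sim)
#> CANN simulation: 20000 tau_s (20000 samples of 80 units), recurrent model
#>   peak rate after transient (1000 tau_s): max 9.21, mean 4.84
classify_regime(sim)
#> Regime: population_spikes (h_max 9.21, modulation 0.58, drift 0.31 rad, oscillation 0.781 rad)
peaks <- detect_peaks(sim, threshold = 6.2)
mean_peak_separation(peaks, midpoint = 0, a = params$a)
#> Cluster separation: 0.934 TW (cluster SDs 0.139 / 0.138 TW, n = 631 / 624)
```

The run is in the population-spike regime; the above-threshold spike
positions form two clusters whose separation (0.93 TW ≈ 90°)
*over-estimates* the true 0.75 TW — the model's analogue of motion
repulsion — with a within-cluster spread of 0.14 TW ≈ 13°.  A
time-averaged profile of the same run (`time_averaged_profile(sim)`) is
still single-peaked: the separation information lives in the temporal
modulation, and `plot(sim)` shows the alternating spike raster.

Other entry points: `resolution_curve()` (perceived separation vs. true
separation), `short_window_resolution()` (500 τ_s windows),
`threshold_resolution_grid()` (threshold sensitivity),
`phase_diagram()` (regime map over input and depression strength),
`bias_conditioned_map()` (spike positions conditioned on the input-bias
history), `run_experiment()` / `replay()` (YAML-configured, exactly
reproducible runs), and `Rscript inst/cli/cann.R` for shell use.

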